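#' Configuration for a synthetic egg-microbiome study
#'
#' Defaults emulate the field design the analysis assumes: nine spawning
#' locations in two river systems (one alpine site in a separate basin, five
#' main-river sites, three tributary sites), pooled egg samples sequenced to
#' roughly 4,780 reads per location (SD 1,165), two water samples
#' compositionally distinct from eggs, one reagent-only negative control
#' carrying 78 contaminant OTUs that leak into real samples, a
#' temperature-driven richness gradient over an incubation of ~45 days with
#' 10-minute logger readings, and 11-locus diploid microsatellite genotypes
#' for the host populations.
#'
#' @param n_locations Number of spawning locations (default 9).
#' @param n_water_samples Water samples at a subset of locations (default 2).
#' @param reads_per_sample_mean,reads_per_sample_sd Read depth distribution
#'   per pooled sample (default 4780 / 1165), truncated below at `min_depth`.
#' @param min_depth Lower truncation of sequencing depth (default 500).
#' @param n_taxa_pool Size of the regional taxon pool (default 600).
#' @param richness_intercept Taxa available at 0 degC (default 80).
#' @param richness_slope Taxa gained per degC (`beta_T`; default 25; 0 gives
#'   the no-effect null).
#' @param richness_driver_periods Which incubation periods' mean temperature
#'   drives richness; `NULL` (default) uses the whole-incubation mean.
#' @param n_periods Number of equal incubation periods used for the weather
#'   process and for `richness_driver_periods` (default 5).
#' @param abundance_sigma Log-normal SD of within-location relative
#'   abundances (default 1.2).
#' @param n_contaminant_otus Contaminant OTUs in the negative control
#'   (default 78).
#' @param contaminant_carryover_prob Probability that a given contaminant
#'   also shows up in a given real sample (default 0.5).
#' @param contaminant_relabund Expected relative abundance contributed by
#'   carried-over contaminants per sample (default 0.02).
#' @param water_shared_fraction Fraction of water-sample taxa drawn from the
#'   egg communities' taxa (default 0.3; the rest come from elsewhere in the
#'   pool, making water compositionally distinct).
#' @param temperature_range Range of mean incubation temperatures across
#'   locations in degC (default `c(2, 6)`; the other-basin alpine site is
#'   pinned to the cold end).
#' @param daily_amplitude Amplitude of the sinusoidal daily cycle in degC
#'   (default 0.5).
#' @param seasonal_trend Linear seasonal trend in degC per day (default
#'   0.01).
#' @param weather_sd,weather_ar SD and AR(1) coefficient of per-period
#'   weather offsets shared within a location (defaults 0.8 and 0.6,
#'   emulating multi-day synoptic regimes).
#' @param noise_sd Logger measurement noise SD in degC (default 0.1).
#' @param incubation_days Days from spawning to sampling (default 45).
#' @param n_loci Microsatellite loci (default 11).
#' @param n_alleles Alleles per locus in the regional pool (default 8).
#' @param n_ind_range Individuals genotyped per population (default 20-36).
#' @param theta_div Host-population divergence knob in `[0, 1)` (default
#'   0.1; 0 gives identical allele frequencies everywhere).
#' @param seed Integer seed; mandatory for reproducible studies.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_locations = 9,
                              n_water_samples = 2,
                              reads_per_sample_mean = 4780,
                              reads_per_sample_sd = 1165,
                              min_depth = 500,
                              n_taxa_pool = 600,
                              richness_intercept = 80,
                              richness_slope = 25,
                              richness_driver_periods = NULL,
                              n_periods = 5,
                              abundance_sigma = 1.2,
                              n_contaminant_otus = 78,
                              contaminant_carryover_prob = 0.5,
                              contaminant_relabund = 0.02,
                              water_shared_fraction = 0.3,
                              temperature_range = c(2, 6),
                              daily_amplitude = 0.5,
                              seasonal_trend = 0.01,
                              weather_sd = 0.8,
                              weather_ar = 0.6,
                              noise_sd = 0.1,
                              incubation_days = 45,
                              n_loci = 11,
                              n_alleles = 8,
                              n_ind_range = c(20, 36),
                              theta_div = 0.1,
                              seed = 1) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_locations >= 1, n_water_samples >= 0,
              n_water_samples <= n_locations,
              reads_per_sample_mean > 0, reads_per_sample_sd >= 0,
              n_taxa_pool >= 2, n_contaminant_otus >= 0,
              n_contaminant_otus < n_taxa_pool,
              contaminant_carryover_prob >= 0,
              contaminant_carryover_prob <= 1,
              water_shared_fraction >= 0, water_shared_fraction <= 1,
              theta_div >= 0, theta_div < 1,
              is.finite(richness_slope), n_periods >= 1,
              incubation_days >= n_periods)
  })
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a random phylogeny over a taxon pool
#'
#' Random coalescent topology with i.i.d. exponential branch lengths
#' (mean 0.1 substitutions/site), deterministic given the seed.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed.
#' @param mean_branch Mean branch length (default 0.1).
#' @param tip_labels Optional tip labels (default `OTU_0001`...).
#' @return A rooted binary [ape::phylo] tree.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, mean_branch = 0.1,
                          tip_labels = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  use_seed(seed)
  tip_labels <- tip_labels %||% sprintf("OTU_%04d", seq_len(n_taxa))
  tree <- ape::rcoal(n_taxa, tip.label = tip_labels)
  tree$edge.length <- rexp(nrow(tree$edge), rate = 1 / mean_branch)
  validate_phylogeny(tree)
  tree
}

# truncated-normal sequencing depth
draw_depth <- function(n, cfg) {
  pmax(cfg$min_depth,
       round(rnorm(n, cfg$reads_per_sample_mean, cfg$reads_per_sample_sd)))
}

# one location's 10-minute temperature series plus its per-period means
simulate_temperature <- function(cfg, base_temp, spawn_date) {
  n_days <- cfg$incubation_days
  step_s <- 600
  times <- seq(from = as.POSIXct(paste(spawn_date, "00:00:00"), tz = "UTC"),
               by = step_s, length.out = n_days * 144L)
  day_frac <- as.numeric(times - times[1], units = "days")
  # AR(1) weather regimes, one offset per incubation period
  period_len <- n_days / cfg$n_periods
  offs <- numeric(cfg$n_periods)
  offs[1] <- rnorm(1, 0, cfg$weather_sd)
  if (cfg$n_periods > 1)
    for (k in 2:cfg$n_periods)
      offs[k] <- cfg$weather_ar * offs[k - 1] +
        rnorm(1, 0, cfg$weather_sd * sqrt(1 - cfg$weather_ar^2))
  period_of <- pmin(floor(day_frac / period_len) + 1L, cfg$n_periods)
  temp <- base_temp +
    cfg$seasonal_trend * (day_frac - n_days / 2) +
    cfg$daily_amplitude * sin(2 * pi * day_frac) +
    offs[period_of] +
    rnorm(length(times), 0, cfg$noise_sd)
  list(timestamps = times, temperature = temp,
       period_means = vapply(seq_len(cfg$n_periods),
                             function(k) mean(temp[period_of == k]),
                             numeric(1)))
}

#' Simulate a complete synthetic study
#'
#' Generates every artifact the analysis pipeline consumes, with known
#' ground truth: per location i with (realized) incubation temperature
#' `T_i`, the available richness is `S_i = round(S0 + beta_T * T_i)`; taxa
#' are drawn from the pool with location-specific log-normal relative
#' abundances and read counts are multinomial at a truncated-normal depth.
#' Water samples use a distinct abundance profile sharing a configurable
#' fraction of taxa with the eggs; the negative control holds the
#' contaminant taxa, which leak into real samples with the configured
#' carryover probability. Host genotypes drift along the river network so
#' that pairwise differentiation increases with `theta_div` and with
#' network distance.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_study` with elements `table`
#'   ([otu_table()], eggs + water + negative control), `tree`, `metadata`,
#'   `temperature` (`temperature_series`), `period_means` (locations x
#'   periods matrix), `genotypes`, `network`, `geo_distance` (along-network,
#'   `lambda_up = 1`), and `ground_truth`.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  use_seed(cfg$seed)
  nl <- cfg$n_locations
  loc_ids <- sprintf("loc_%02d", seq_len(nl))
  otu_ids <- sprintf("OTU_%04d", seq_len(cfg$n_taxa_pool))

  # river groups: location 1 sits in a separate basin; roughly the first
  # 60% of the remainder lie along the main river, the rest are tributaries
  n_main <- max(1L, round((nl - 1L) * 0.6))
  river_group <- c("other_basin", rep("main_river", n_main),
                   rep("tributary", nl - 1L - n_main))

  # mean incubation temperature per location; the alpine other-basin site
  # is pinned to the cold end of the range
  base_temp <- runif(nl, cfg$temperature_range[1], cfg$temperature_range[2])
  base_temp[1] <- cfg$temperature_range[1]

  # spawning dates staggered within a fortnight around Jan 1st
  spawn <- as.Date("2010-01-01") + sample.int(14, nl, replace = TRUE) - 7L
  sample_date <- spawn + cfg$incubation_days

  # temperature series and realized period means
  temps <- vector("list", nl)
  period_means <- matrix(NA_real_, nl, cfg$n_periods,
                         dimnames = list(loc_ids,
                                         paste0("period_", seq_len(cfg$n_periods))))
  for (i in seq_len(nl)) {
    temps[[i]] <- simulate_temperature(cfg, base_temp[i], spawn[i])
    period_means[i, ] <- temps[[i]]$period_means
  }
  driver <- cfg$richness_driver_periods %||% seq_len(cfg$n_periods)
  t_eff <- rowMeans(period_means[, driver, drop = FALSE])
  t_overall <- rowMeans(period_means)

  # available richness per location
  S <- round(cfg$richness_intercept + cfg$richness_slope * t_eff)
  if (any(S <= 0))
    stop("config error: non-positive true richness at some location; ",
         "adjust richness_intercept/richness_slope", call. = FALSE)
  contaminants <- otu_ids[seq_len(cfg$n_contaminant_otus)]
  clean_pool <- setdiff(otu_ids, contaminants)
  if (any(S > length(clean_pool)))
    stop("config error: true richness exceeds the non-contaminant pool",
         call. = FALSE)

  # egg communities
  egg_ids <- sprintf("egg_%s", loc_ids)
  counts <- matrix(0L, nl + cfg$n_water_samples + 1L, cfg$n_taxa_pool,
                   dimnames = list(NULL, otu_ids))
  used_taxa <- character(0)
  for (i in seq_len(nl)) {
    taxa <- sample(clean_pool, S[i])
    used_taxa <- union(used_taxa, taxa)
    w <- exp(rnorm(S[i], 0, cfg$abundance_sigma))
    depth <- draw_depth(1, cfg)
    counts[i, taxa] <- as.integer(rmultinom(1, depth, w / sum(w)))
  }

  # water samples at the last n_water_samples locations: distinct profile,
  # sharing a configurable fraction of taxa with the egg communities
  water_locs <- if (cfg$n_water_samples > 0)
    loc_ids[seq.int(nl, by = -1L, length.out = cfg$n_water_samples)]
  else character(0)
  water_ids <- sprintf("water_%s", water_locs)
  S_water <- round(mean(S))
  for (k in seq_along(water_ids)) {
    n_shared <- round(cfg$water_shared_fraction * S_water)
    n_shared <- min(n_shared, length(used_taxa))
    own_pool <- setdiff(clean_pool, used_taxa)
    taxa <- c(sample(used_taxa, n_shared),
              sample(own_pool, min(S_water - n_shared, length(own_pool))))
    w <- exp(rnorm(length(taxa), 0, cfg$abundance_sigma))
    depth <- draw_depth(1, cfg)
    counts[nl + k, taxa] <- as.integer(rmultinom(1, depth, w / sum(w)))
  }

  # negative control: every contaminant detected at least once
  control_id <- "negative_control"
  ci <- nl + cfg$n_water_samples + 1L
  if (cfg$n_contaminant_otus > 0) {
    depth <- draw_depth(1, cfg)
    w <- exp(rnorm(cfg$n_contaminant_otus, 0, cfg$abundance_sigma))
    extra <- max(depth - cfg$n_contaminant_otus, 0)
    counts[ci, contaminants] <- 1L +
      as.integer(rmultinom(1, extra, w / sum(w)))
  }

  # contaminant carryover into real samples
  if (cfg$n_contaminant_otus > 0 && cfg$contaminant_carryover_prob > 0) {
    for (r in seq_len(nl + cfg$n_water_samples)) {
      carried <- runif(cfg$n_contaminant_otus) < cfg$contaminant_carryover_prob
      if (!any(carried)) next
      lam <- sum(counts[r, ]) * cfg$contaminant_relabund /
        cfg$n_contaminant_otus
      counts[r, contaminants[carried]] <-
        counts[r, contaminants[carried]] + 1L + rpois(sum(carried), lam)
    }
  }

  sample_ids <- c(egg_ids, water_ids, control_id)
  rownames(counts) <- sample_ids
  table <- otu_table(counts)

  # phylogeny over the full pool
  tree <- simulate_tree(cfg$n_taxa_pool, seed = NULL, tip_labels = otu_ids)

  # geometry: a main-river chain fed by tributaries, plus the separate basin
  network <- simulate_network(loc_ids, river_group)
  geo <- corrected_geo_distance(
    network,
    locations = loc_ids[river_group != "other_basin"], lambda_up = 1)

  # metadata (water samples inherit their location's coordinates and dates)
  coords <- network$nodes[match(network$locations$node_id[
    match(loc_ids, network$locations$location_id)],
    network$nodes$node_id), ]
  md <- data.frame(
    sample_id = sample_ids,
    location_id = c(loc_ids, water_locs, loc_ids[1]),
    sample_type = c(rep("egg", nl), rep("water", length(water_ids)),
                    "negative_control"),
    river_group = c(river_group,
                    river_group[match(water_locs, loc_ids)],
                    river_group[1]),
    stringsAsFactors = FALSE)
  loc_row <- match(md$location_id, loc_ids)
  md$latitude <- coords$latitude[loc_row]
  md$longitude <- coords$longitude[loc_row]
  md$elevation_m <- coords$elevation_m[loc_row]
  md$spawn_date <- spawn[loc_row]
  md$sample_date <- sample_date[loc_row]
  md <- validate_metadata(md)

  # temperature series long-form table
  ts <- do.call(rbind, lapply(seq_len(nl), function(i)
    data.frame(location_id = loc_ids[i],
               timestamp = temps[[i]]$timestamps,
               temperature_c = temps[[i]]$temperature,
               stringsAsFactors = FALSE)))
  ts <- validate_temperature_series(ts)

  genotypes <- simulate_genotypes(cfg, loc_ids, river_group, network)

  study <- list(
    table = table, tree = tree, metadata = md, temperature = ts,
    period_means = period_means, genotypes = genotypes, network = network,
    geo_distance = geo,
    ground_truth = list(
      true_richness = setNames(S, loc_ids),
      mean_temperature = setNames(t_overall, loc_ids),
      driver_temperature = setNames(t_eff, loc_ids),
      richness_slope = cfg$richness_slope,
      richness_driver_periods = driver,
      theta_div = cfg$theta_div,
      contaminant_otus = contaminants,
      egg_sample_ids = egg_ids,
      water_sample_ids = water_ids,
      control_sample_id = control_id))
  class(study) <- "synthetic_study"
  study
}

# synthetic river geometry: a chain of main-river nodes (~12 km apart)
# running north, tributary nodes hanging off it (~6 km), and a disconnected
# node for the separate basin
simulate_network <- function(loc_ids, river_group) {
  nl <- length(loc_ids)
  node_ids <- paste0("node_", loc_ids)
  main_idx <- which(river_group == "main_river")
  trib_idx <- which(river_group == "tributary")
  other_idx <- which(river_group == "other_basin")
  lat <- 46.7 + 0.03 * seq_len(nl); lon <- rep(7.45, nl)
  elev <- 640 - 15 * seq_len(nl)
  lat[other_idx] <- 46.43; lon[other_idx] <- 9.75; elev[other_idx] <- 1802
  nodes <- data.frame(node_id = node_ids, latitude = lat, longitude = lon,
                      elevation_m = elev, stringsAsFactors = FALSE)
  edges <- NULL
  if (length(main_idx) > 1) {
    up <- node_ids[main_idx]
    edges <- data.frame(from = up[-length(up)], to = up[-1],
                        length_km = 8 + 8 * runif(length(up) - 1),
                        stringsAsFactors = FALSE)
  }
  # each tributary joins a main-river node
  for (k in seq_along(trib_idx)) {
    join <- node_ids[main_idx[1 + (k - 1) %% length(main_idx)]]
    edges <- rbind(edges, data.frame(
      from = node_ids[trib_idx[k]], to = join,
      length_km = 3 + 5 * runif(1), stringsAsFactors = FALSE))
  }
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        length_km = numeric(0))
  river_network(nodes, edges,
                data.frame(location_id = loc_ids, node_id = node_ids,
                           stringsAsFactors = FALSE))
}

# Balding-Nichols-style divergence: each population's allele frequencies
# are drawn independently from Dirichlet(pool * (1 - theta_k)/theta_k)
# around the regional pool, with the effective theta_k scaled by the
# population's along-network distance from the most upstream site (the
# separate basin gets the largest scale), so pairwise differentiation
# grows with theta_div and, on average, with network separation
simulate_genotypes <- function(cfg, loc_ids, river_group, network) {
  nl <- length(loc_ids)
  n_ind <- sample(seq(cfg$n_ind_range[1], cfg$n_ind_range[2]), nl,
                  replace = TRUE)
  connected <- which(river_group != "other_basin")
  dist_scale <- rep(1, nl)
  if (length(connected) > 1) {
    geo <- corrected_geo_distance(network, loc_ids[connected],
                                  lambda_up = 1)
    d0 <- geo[1, ]                       # from the most upstream site
    dist_scale[connected] <- 0.5 + d0 / max(mean(d0), 1e-9)
  }
  dist_scale[river_group == "other_basin"] <- 3  # separate basin
  loci <- matrix(NA_character_, sum(n_ind), cfg$n_loci)
  pop_col <- rep(loc_ids, n_ind)
  ind_col <- unlist(lapply(seq_len(nl), function(k)
    sprintf("%s_ind%02d", loc_ids[k], seq_len(n_ind[k]))))
  for (l in seq_len(cfg$n_loci)) {
    pool <- rdirichlet(rep(1, cfg$n_alleles))
    freqs <- matrix(NA_real_, nl, cfg$n_alleles)
    for (k in seq_len(nl)) {
      theta_k <- min(cfg$theta_div * dist_scale[k], 0.95)
      if (theta_k == 0) {
        freqs[k, ] <- pool
      } else {
        conc <- (1 - theta_k) / theta_k
        freqs[k, ] <- rdirichlet(pool * conc + 1e-9)
      }
    }
    allele_names <- as.character(100 + 4 * seq_len(cfg$n_alleles))
    col <- character(0)
    for (k in seq_len(nl)) {
      a1 <- sample(allele_names, n_ind[k], replace = TRUE,
                   prob = freqs[k, ])
      a2 <- sample(allele_names, n_ind[k], replace = TRUE,
                   prob = freqs[k, ])
      col <- c(col, paste(a1, a2, sep = "/"))
    }
    loci[, l] <- col
  }
  colnames(loci) <- sprintf("locus_%02d", seq_len(cfg$n_loci))
  genotype_table(pop_col, ind_col, loci)
}

#' Simulate amplicon reads for one sample
#'
#' One read per count unit: a 10-bp barcode, the 16S primer, then a 311-bp
#' taxon-specific template (deterministic per OTU id). Configurable
#' fractions of reads are corrupted for exercising the quality filter:
#' `barcode` (one barcode base flipped), `truncation` (template cut below
#' 300 bp), `ambiguity` (three template bases replaced by `N`). Reads are
#' assigned to categories independently (multinomial).
#'
#' @param otu_counts Named non-negative integer vector for one sample.
#' @param barcode 10-bp sample barcode.
#' @param primer Primer sequence.
#' @param error_profile Named list/vector with `barcode`, `truncation`,
#'   `ambiguity` fractions summing to at most 1 (default all 0).
#' @param seed Integer seed.
#' @param template_length Amplicon template length (default 311).
#' @return Named character vector of reads (names are read ids).
#' @export
simulate_reads <- function(otu_counts, barcode, primer,
                           error_profile = c(barcode = 0, truncation = 0,
                                             ambiguity = 0),
                           seed = NULL, template_length = 311) {
  check_counts(otu_counts)
  if (nchar(barcode) != 10)
    stop("barcode must be 10 bp", call. = FALSE)
  ep <- as.list(error_profile)
  fr <- c(ep$barcode %||% 0, ep$truncation %||% 0, ep$ambiguity %||% 0)
  if (sum(fr) > 1) stop("corruption fractions sum > 1", call. = FALSE)
  use_seed(seed)
  bases <- c("A", "C", "G", "T")
  taxa <- rep(names(otu_counts), otu_counts)
  n <- length(taxa)
  if (n == 0) return(setNames(character(0), character(0)))
  if (!exists(".Random.seed", envir = globalenv())) runif(1)
  templates <- vapply(unique(taxa), function(id) {
    # deterministic per-taxon template independent of the read RNG stream
    rs <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id))) %% 2147483647
    old <- get(".Random.seed", envir = globalenv())
    set.seed(rs)
    s <- paste(sample(bases, template_length, replace = TRUE), collapse = "")
    assign(".Random.seed", old, envir = globalenv())
    s
  }, character(1))
  reads <- paste0(barcode, primer, templates[taxa])
  cat_draw <- sample.int(4L, n, replace = TRUE,
                         prob = c(fr, 1 - sum(fr)))
  for (i in which(cat_draw == 1L)) {  # corrupt one barcode base
    pos <- sample.int(10L, 1)
    old_b <- substr(reads[i], pos, pos)
    substr(reads[i], pos, pos) <- sample(setdiff(bases, old_b), 1)
  }
  for (i in which(cat_draw == 2L)) {  # truncate template below 300 bp
    keep <- sample(250:299, 1)
    reads[i] <- substr(reads[i], 1, nchar(barcode) + nchar(primer) + keep)
  }
  for (i in which(cat_draw == 3L)) {  # three ambiguous bases
    off <- nchar(barcode) + nchar(primer)
    pos <- off + sample.int(template_length, 3)
    for (p in pos) substr(reads[i], p, p) <- "N"
  }
  setNames(reads, sprintf("read_%06d_%s", seq_len(n), taxa))
}

#' Write reads as FASTA
#' @param reads Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA path.
#' @return Named character vector (names truncated at first whitespace).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}
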
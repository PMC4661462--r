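#' Pipeline configuration
#'
#' One configuration object drives the full workflow
#' (simulate -> decontaminate -> diversity -> community tests -> spatial /
#' host genetics -> temperature). Defaults follow the study design:
#' 99,999 permutations for all permutation tests, 1,000 bootstrap
#' replicates, core-microbiome prevalence fraction 0.77, FDR 0.05 with a
#' 5% mean-difference filter, stepwise entry p 0.05.
#'
#' @param simulate A [simulation_config()] (its seed is overridden by
#'   `seed`), or `NULL` to analyse supplied inputs.
#' @param inputs Optional named list of pre-loaded study components (same
#'   shape as a `synthetic_study`); used when `simulate` is `NULL`.
#' @param out_dir Output directory for all artifacts.
#' @param n_permutations Permutations for Mantel/PERMANOVA/ANOSIM/
#'   dispersion tests (default 99999).
#' @param bootstrap_B Bootstrap replicates (default 1000).
#' @param core_fraction Core-microbiome prevalence fraction (default 0.77).
#' @param fdr_level BH threshold for differential features (default 0.05).
#' @param min_mean_diff Mean-difference filter (default 0.05).
#' @param entry_p Stepwise entry threshold (default 0.05).
#' @param rarefaction_reps Rarefaction replicates for alpha diversity
#'   (default 10).
#' @param n_periods Incubation periods for the temperature regression
#'   (default 5).
#' @param lambda_up Upstream cost multiplier for corrected river distances
#'   (default 2; plain distances at 1 are always reported alongside).
#' @param seed Master seed; every stochastic stage derives its own
#'   sub-seed from it (mandatory).
#' @param stages Stage gating: any subset of
#'   `c("simulate", "qc", "diversity", "community", "spatial",
#'   "temperature")`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = simulation_config(),
                            inputs = NULL,
                            out_dir = tempfile("eggbiome_run_"),
                            n_permutations = 99999,
                            bootstrap_B = 1000,
                            core_fraction = 0.77,
                            fdr_level = 0.05,
                            min_mean_diff = 0.05,
                            entry_p = 0.05,
                            rarefaction_reps = 10,
                            n_periods = 5,
                            lambda_up = 2,
                            seed = 1,
                            stages = c("simulate", "qc", "diversity",
                                       "community", "spatial",
                                       "temperature")) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            n_permutations >= 1, bootstrap_B >= 1,
            core_fraction > 0, core_fraction <= 1,
            fdr_level > 0, fdr_level < 1,
            min_mean_diff >= 0, entry_p > 0, entry_p < 1)
  if (is.null(simulate) && is.null(inputs))
    stop("either a simulate block or inputs are required", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in fixed order, writes every intermediate
#' in the package's file formats plus a machine-readable `results.json`,
#' and logs versions, seed and per-stage wall time to `run_log.txt`
#' (timestamps live only in the log, so result payloads are byte-identical
#' across reruns with the same configuration and seed). A stage failure
#' halts the run with the failing stage named; partial outputs are kept.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly; the aggregated results list is
#'   attached as attribute `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run_log.txt")
  log_lines <- c(sprintf("eggbiome %s | R %s | seed %d",
                         as.character(utils::packageVersion("eggbiome")),
                         paste(R.version$major, R.version$minor, sep = "."),
                         as.integer(config$seed)))
  results <- list()
  stage <- function(name, expr) {
    if (!name %in% config$stages) return(NULL)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage %-12s %8.2f s", name,
                                       proc.time()[["elapsed"]] - t0))
    writeLines(log_lines, log_path)
    res
  }

  # --- simulate or load -----------------------------------------------
  study <- stage("simulate", {
    if (!is.null(config$simulate)) {
      sc <- config$simulate
      sc$seed <- sub_seed(config$seed, "simulate")
      st <- simulate_study(sc)
      write_otu_table(st$table, file.path(out, "otu_table.tsv"))
      write_phylogeny(st$tree, file.path(out, "tree.nwk"))
      write_metadata(st$metadata, file.path(out, "metadata.tsv"))
      write_temperature_series(st$temperature,
                               file.path(out, "temperature.tsv"))
      write_genotypes(st$genotypes, file.path(out, "genotypes.tsv"))
      write_distance_matrix(st$geo_distance,
                            file.path(out, "geo_distance.tsv"))
      gt <- st$ground_truth
      gt_df <- data.frame(location_id = names(gt$true_richness),
                          true_richness = unname(gt$true_richness),
                          mean_temperature = unname(gt$mean_temperature),
                          stringsAsFactors = FALSE)
      write.table(gt_df, file.path(out, "ground_truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      st
    } else config$inputs
  })
  if (is.null(study)) study <- config$inputs
  if (is.null(study)) stop("no study to analyse", call. = FALSE)
  md <- study$metadata

  # --- qc: negative-control decontamination ---------------------------
  filtered <- stage("qc", {
    dec <- remove_control_otus(study$table, md)
    write_otu_table(dec$table, file.path(out, "otu_table_filtered.tsv"))
    writeLines(dec$removed_otus, file.path(out, "removed_otus.txt"))
    dec
  })
  table_f <- if (!is.null(filtered)) filtered$table else study$table
  md_f <- md[md$sample_type != "negative_control", ]

  egg_ids <- md_f$sample_id[md_f$sample_type == "egg"]
  loc_of <- setNames(md_f$location_id, md_f$sample_id)
  egg_locs <- unname(loc_of[egg_ids])

  # --- diversity -------------------------------------------------------
  div <- stage("diversity", {
    seed_d <- sub_seed(config$seed, "diversity")
    egg_table <- otu_table(unclass_otu(table_f)[egg_ids, , drop = FALSE])
    alpha <- alpha_table(egg_table, study$tree,
                         n_reps = config$rarefaction_reps, seed = seed_d)
    curves <- rarefaction_curves(egg_table, study$tree, n_reps = 3,
                                 seed = seed_d + 1L)
    beta <- unifrac(table_f, study$tree, weighted = FALSE)
    pc <- principal_coordinates(beta)
    write.table(alpha, file.path(out, "alpha.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(curves, file.path(out, "rarefaction.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_distance_matrix(beta, file.path(out, "unifrac.tsv"))
    write.table(data.frame(sample_id = rownames(pc$coordinates),
                           pc$coordinates, check.names = FALSE),
                file.path(out, "pcoa.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(alpha = alpha, curves = curves, beta = beta, pcoa = pc)
  })

  if (!is.null(div)) {
    results$alpha <- div$alpha
    results$beta <- list(metric = "unweighted_unifrac",
                         n_samples = nrow(div$beta))
  }

  # --- community tests -------------------------------------------------
  comm <- stage("community", {
    seed_c <- sub_seed(config$seed, "community")
    beta <- div$beta
    # main river vs tributaries, egg samples in the connected system
    grp_ids <- md_f$sample_id[md_f$sample_type == "egg" &
                                md_f$river_group %in%
                                  c("main_river", "tributary")]
    labels <- setNames(md_f$river_group[match(grp_ids, md_f$sample_id)],
                       grp_ids)
    dd <- div$beta[grp_ids, grp_ids]
    perm <- permanova(dd, labels, n_perm = config$n_permutations,
                      seed = seed_c)
    anos <- anosim_test(dd, labels, n_perm = config$n_permutations,
                        seed = seed_c + 1L)
    disp <- dispersion_test(dd, labels, n_perm = config$n_permutations,
                            seed = seed_c + 2L)
    # bootstrap: other-basin egg community vs main-river group, and each
    # water sample vs the egg communities of the connected system
    boots <- list()
    ob <- md_f$sample_id[md_f$sample_type == "egg" &
                           md_f$river_group == "other_basin"]
    main_ids <- md_f$sample_id[md_f$sample_type == "egg" &
                                 md_f$river_group == "main_river"]
    if (length(ob) == 1 && length(main_ids) >= 2)
      boots[[paste0(ob, "_vs_main_river")]] <-
        bootstrap_one_vs_group(table_f, study$tree, ob, main_ids,
                               B = config$bootstrap_B,
                               seed = seed_c + 3L)
    water_ids <- md_f$sample_id[md_f$sample_type == "water"]
    conn_eggs <- md_f$sample_id[md_f$sample_type == "egg" &
                                  md_f$river_group != "other_basin"]
    for (wid in water_ids)
      boots[[paste0(wid, "_vs_eggs")]] <-
        bootstrap_one_vs_group(table_f, study$tree, wid, conn_eggs,
                               B = config$bootstrap_B,
                               seed = seed_c + 10L + match(wid, water_ids))
    core <- core_microbiome(
      otu_table(unclass_otu(table_f)[egg_ids, , drop = FALSE]),
      min_fraction = config$core_fraction)
    # differential relative abundances, eggs vs water
    difff <- NULL
    if (length(water_ids) >= 2 && length(egg_ids) >= 2) {
      sel <- c(egg_ids, water_ids)
      rel <- unclass_otu(table_f)[sel, , drop = FALSE]
      rel <- rel / rowSums(rel)
      difff <- differential_features(
        rel, setNames(md_f$sample_type[match(sel, md_f$sample_id)], sel),
        fdr_level = config$fdr_level,
        min_mean_diff = config$min_mean_diff)
      write.table(difff, file.path(out, "differential_features.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(core, file.path(out, "core_otus.txt"))
    boot_lines <- vapply(names(boots), function(nm)
      paste0(nm, ": ", format(boots[[nm]])), character(1))
    writeLines(boot_lines, file.path(out, "bootstrap_report.txt"))
    list(permanova = perm, anosim = anos, dispersion = disp,
         bootstrap = boots, core = core, differential = difff)
  })
  if (!is.null(comm)) {
    results$permanova <- list(pseudo_F = comm$permanova$pseudo_F,
                              R2 = comm$permanova$R2,
                              p = comm$permanova$p)
    results$anosim <- list(R = comm$anosim$R, p = comm$anosim$p)
    results$dispersion <- list(F = comm$dispersion$F,
                               df1 = comm$dispersion$df1,
                               p = comm$dispersion$p)
    results$bootstrap <- lapply(comm$bootstrap, function(b)
      list(null_mean = b$null_mean, ci_lower = b$ci_lower,
           ci_upper = b$ci_upper, observed = b$observed_distance,
           p = b$p, report = format(b)))
    results$core <- list(n_core = length(comm$core),
                         min_fraction = config$core_fraction)
  }

  # --- spatial / host genetics ----------------------------------------
  spat <- stage("spatial", {
    seed_s <- sub_seed(config$seed, "spatial")
    conn_locs <- md_f$location_id[md_f$sample_type == "egg" &
                                    md_f$river_group != "other_basin"]
    egg_of_loc <- setNames(
      md_f$sample_id[md_f$sample_type == "egg"],
      md_f$location_id[md_f$sample_type == "egg"])
    u_loc <- div$beta[egg_of_loc[conn_locs], egg_of_loc[conn_locs]]
    dimnames(u_loc) <- list(conn_locs, conn_locs)
    geo1 <- corrected_geo_distance(study$network, conn_locs, lambda_up = 1)
    geoL <- corrected_geo_distance(study$network, conn_locs,
                                   lambda_up = config$lambda_up)
    man1 <- mantel_test(u_loc, geo1, n_perm = config$n_permutations,
                        tail = "greater", seed = seed_s)
    manL <- mantel_test(u_loc, geoL, n_perm = config$n_permutations,
                        tail = "greater", seed = seed_s + 1L)
    # control for temperature differences
    mt <- vapply(conn_locs, function(l)
      mean(study$ground_truth$mean_temperature[l]), numeric(1))
    tdiff <- abs(outer(mt, mt, "-"))
    dimnames(tdiff) <- dimnames(geo1)
    pman <- partial_mantel_test(u_loc, geo1, tdiff,
                                n_perm = config$n_permutations,
                                tail = "greater", seed = seed_s + 2L)
    dest <- jost_dest(study$genotypes)
    dest_conn <- dest$pairwise[conn_locs, conn_locs]
    man_dest <- mantel_test(u_loc, dest_conn,
                            n_perm = config$n_permutations,
                            tail = "greater", seed = seed_s + 3L)
    slopes <- slope_convergence(u_loc, geoL,
                                max_removed = max(0L, nrow(u_loc) - 4L),
                                n_draws = 100, seed = seed_s + 4L)
    write_distance_matrix(dest$pairwise, file.path(out, "dest.tsv"))
    write.table(slopes$summary, file.path(out, "slope_convergence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(mantel_geo = man1, mantel_geo_corrected = manL,
         partial_mantel = pman, dest = dest, mantel_dest = man_dest,
         slopes = slopes)
  })
  if (!is.null(spat)) {
    results$mantel <- list(
      geo = list(r = spat$mantel_geo$r, p = spat$mantel_geo$p),
      geo_corrected = list(r = spat$mantel_geo_corrected$r,
                           p = spat$mantel_geo_corrected$p),
      dest = list(r = spat$mantel_dest$r, p = spat$mantel_dest$p))
    results$partial_mantel <- list(
      geo_controlling_temperature = list(r = spat$partial_mantel$r,
                                         p = spat$partial_mantel$p))
    results$dest <- list(
      mean_pairwise = mean(lower_tri(spat$dest$pairwise)))
    results$slopes <- list(
      full_slope = spat$slopes$summary$mean[1],
      max_sd = max(spat$slopes$summary$sd))
  }

  # --- temperature ----------------------------------------------------
  temp <- stage("temperature", {
    seed_t <- sub_seed(config$seed, "temperature")
    egg_md <- md_f[md_f$sample_type == "egg", ]
    pm_list <- lapply(seq_len(nrow(egg_md)), function(i)
      period_means(study$temperature, egg_md$spawn_date[i],
                   egg_md$sample_date[i], k = config$n_periods,
                   location_id = egg_md$location_id[i]))
    pm_mat <- do.call(rbind, lapply(pm_list, function(p) p$period_means))
    rownames(pm_mat) <- egg_md$location_id
    colnames(pm_mat) <- paste0("period_", seq_len(config$n_periods))
    overall <- setNames(vapply(pm_list, function(p) p$overall_mean,
                               numeric(1)), egg_md$location_id)
    conn_locs <- egg_md$location_id[egg_md$river_group != "other_basin"]
    egg_of_loc <- setNames(egg_md$sample_id, egg_md$location_id)
    u_loc <- div$beta[egg_of_loc[conn_locs], egg_of_loc[conn_locs]]
    dimnames(u_loc) <- list(conn_locs, conn_locs)
    geo1 <- corrected_geo_distance(study$network, conn_locs, lambda_up = 1)
    assoc <- temperature_association(
      div$alpha, overall, u_loc, geo1,
      location_of = setNames(egg_md$location_id, egg_md$sample_id),
      n_perm = config$n_permutations, seed = seed_t)
    # stepwise per metric on the five period means
    sw <- list()
    for (met in unique(div$alpha$metric)) {
      sub <- div$alpha[div$alpha$metric == met, ]
      yy <- sub$mean[match(egg_md$sample_id, sub$sample_id)]
      sw[[met]] <- forward_stepwise(yy, pm_mat, entry_p = config$entry_p)
    }
    write.table(data.frame(location_id = rownames(pm_mat), pm_mat,
                           overall_mean = overall, check.names = FALSE),
                file.path(out, "period_means.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(period_means = pm_mat, overall = overall, association = assoc,
         stepwise = sw)
  })
  if (!is.null(temp)) {
    results$kendall <- lapply(temp$association$kendall, function(k)
      list(tau = k$tau, z = k$z, p = k$p))
    if (!is.null(temp$association$partial_mantel))
      results$partial_mantel$temperature_controlling_geo <- list(
        r = temp$association$partial_mantel$r,
        p = temp$association$partial_mantel$p)
    results$stepwise <- lapply(temp$stepwise, function(s)
      list(selected = s$selected,
           model_F = if (nrow(s$steps) > 0)
             s$steps$model_F[nrow(s$steps)] else NA,
           model_p = if (nrow(s$steps) > 0)
             s$steps$model_p[nrow(s$steps)] else NA,
           R2 = if (nrow(s$steps) > 0)
             s$steps$cumulative_R2[nrow(s$steps)] else 0))
  }

  jsonlite::write_json(results, file.path(out, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(log_lines, "done"), log_path)
  out_ret <- out
  attr(out_ret, "results") <- results
  invisible(out_ret)
}
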
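#' Chao 1 richness estimator
#'
#' Nonparametric richness estimate from singleton and doubleton counts.
#' The default is the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` (finite even when no doubletons are
#' observed); the classic form `S_obs + F1^2 / (2 F2)` is available with
#' `bias_corrected = FALSE`.
#'
#' @param counts Non-negative integer vector of one sample's OTU counts,
#'   at least one positive.
#' @param bias_corrected Use the bias-corrected form (default `TRUE`).
#' @return The Chao 1 estimate (>= observed richness).
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  check_counts(counts)
  if (all(counts == 0)) stop("all-zero sample", call. = FALSE)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0) s_obs + f1 * (f1 - 1) / 2 else s_obs + f1^2 / (2 * f2)
  }
}

#' Number of observed species
#'
#' @param counts Non-negative integer vector of OTU counts.
#' @return Integer count of OTUs with a positive count.
#' @export
observed_species <- function(counts) {
  check_counts(counts)
  sum(counts > 0)
}

check_counts <- function(counts) {
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  invisible(counts)
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting all taxa present in
#' the sample and the root (root connection included, matching the QIIME
#' convention; set `include_root = FALSE` to span only the present tips'
#' most recent common ancestor subtree).
#'
#' @param counts Named non-negative integer vector of OTU counts; names of
#'   positive entries must be tips of `tree`.
#' @param tree Rooted phylogeny with branch lengths.
#' @param include_root Include the path to the root (default `TRUE`).
#' @return Faith's PD (0 for an empty community).
#' @export
faith_pd <- function(counts, tree, include_root = TRUE) {
  faith_pd_impl(counts, tree, include_root, branch_incidence(tree))
}

faith_pd_impl <- function(counts, tree, include_root, bi) {
  check_counts(counts)
  present <- names(counts)[counts > 0]
  if (length(present) == 0) return(0)
  missing_tips <- setdiff(present, tree$tip.label)
  if (length(missing_tips) > 0)
    stop("present OTUs missing from the tree: ",
         paste(utils::head(missing_tips, 5), collapse = ", "), call. = FALSE)
  on_path <- bi$incidence[, present, drop = FALSE]
  covered <- rowSums(on_path) > 0
  if (!include_root) {
    # drop edges ancestral to the MRCA of the present tips, i.e. covered
    # edges leading to every present tip
    if (length(present) == 1) return(0)
    covered <- covered & rowSums(on_path) < length(present)
  }
  sum(bi$lengths[covered])
}

#' Rarefy one sample's counts to a fixed depth
#'
#' Subsamples reads without replacement (multivariate hypergeometric), the
#' standard device for fair diversity comparison across unequal sequencing
#' depths.
#'
#' @param counts Named non-negative integer count vector.
#' @param depth Target depth, `<= sum(counts)`.
#' @param seed Optional integer seed for determinism.
#' @return Integer vector of the same length and names, summing to `depth`.
#' @export
rarefy_counts <- function(counts, depth, seed = NULL) {
  check_counts(counts)
  total <- sum(counts)
  if (depth > total)
    stop("depth (", depth, ") exceeds total count (", total, ")",
         call. = FALSE)
  use_seed(seed)
  if (depth == total) return(as.integer(counts) |> setNames(names(counts)))
  reads <- rep.int(seq_along(counts), counts)
  take <- sample(reads, depth, replace = FALSE)
  out <- tabulate(take, nbins = length(counts))
  setNames(as.integer(out), names(counts))
}

#' Alpha diversity table with rarefaction
#'
#' Computes Chao 1, observed species and Faith's PD per sample as the mean
#' (and SD) over `n_reps` rarefactions at a common depth. The default depth
#' is the minimum sample depth, the most conservative common depth.
#'
#' @param table An [otu_table()].
#' @param tree Rooted phylogeny (required for Faith's PD; `NULL` skips it).
#' @param depth Rarefaction depth; default `min(rowSums(table))`.
#' @param n_reps Rarefaction replicates (default 10). With `n_reps = 1` and
#'   `depth` equal to each sample's own total the metrics are computed on
#'   the raw counts.
#' @param seed Integer seed.
#' @return Data frame: `sample_id`, `metric`, `depth`, `n_reps`, `mean`,
#'   `sd`.
#' @export
alpha_table <- function(table, tree = NULL, depth = NULL, n_reps = 10,
                        seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  m <- unclass_otu(table)
  depth <- depth %||% min(rowSums(m))
  use_seed(seed)
  bi <- if (!is.null(tree)) branch_incidence(tree)
  metrics <- c("chao1", "observed_species", if (!is.null(tree)) "faith_pd")
  rows <- list()
  for (s in rownames(m)) {
    vals <- matrix(NA_real_, n_reps, length(metrics),
                   dimnames = list(NULL, metrics))
    for (r in seq_len(n_reps)) {
      x <- rarefy_counts(m[s, ], min(depth, sum(m[s, ])))
      vals[r, "chao1"] <- chao1(x)
      vals[r, "observed_species"] <- observed_species(x)
      if (!is.null(tree)) vals[r, "faith_pd"] <-
        faith_pd_impl(x, tree, TRUE, bi)
    }
    for (met in metrics)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, metric = met, depth = depth, n_reps = n_reps,
        mean = mean(vals[, met]),
        sd = if (n_reps > 1) sd(vals[, met]) else 0,
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Rarefaction curves
#'
#' Mean (and SD) of each alpha metric over `n_reps` rarefactions at an even
#' grid of depths up to each sample's own total.
#'
#' @inheritParams alpha_table
#' @param depths Depth grid; default 10 evenly spaced depths up to the
#'   minimum sample depth.
#' @return Data frame: `sample_id`, `metric`, `depth`, `mean`, `sd`.
#' @export
rarefaction_curves <- function(table, tree = NULL, depths = NULL,
                               n_reps = 10, seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  m <- unclass_otu(table)
  depths <- depths %||%
    unique(round(seq(1, min(rowSums(m)), length.out = 10)))
  use_seed(seed)
  bi <- if (!is.null(tree)) branch_incidence(tree)
  rows <- list()
  for (s in rownames(m)) for (d in depths) {
    if (d > sum(m[s, ])) next
    a <- replicate(n_reps, {
      x <- rarefy_counts(m[s, ], d)
      c(chao1 = chao1(x), observed_species = observed_species(x),
        faith_pd = if (!is.null(tree)) faith_pd_impl(x, tree, TRUE, bi)
                   else NA_real_)
    })
    for (met in rownames(a)) {
      if (all(is.na(a[met, ]))) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, metric = met, depth = d,
        mean = mean(a[met, ]), sd = if (n_reps > 1) sd(a[met, ]) else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
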
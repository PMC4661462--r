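# edge-presence vectors for a set of samples (edges x samples), plus the
# branch-length vector; shared machinery for the read-resampling bootstrap
edge_presence_of <- function(bi, counts_matrix, tip_order) {
  P <- matrix(0, nrow(counts_matrix), length(tip_order),
              dimnames = list(rownames(counts_matrix), tip_order))
  common <- intersect(colnames(counts_matrix), tip_order)
  P[, common] <- counts_matrix[, common]
  (bi$incidence %*% t(P > 0)) > 0
}

# unweighted UniFrac between one branch-presence column and many
unifrac_one_vs_many <- function(b_query, B_members, w) {
  s_q <- sum(w[b_query])
  s_m <- colSums(B_members * w)
  both <- as.vector(crossprod(B_members * w, b_query))
  uni <- s_q + s_m - 2 * both
  tot <- s_q + s_m - both
  ifelse(tot > 0, uni / tot, 0)
}

#' Bootstrap test of one community against a group
#'
#' Compares the bacterial community of a single query sample against a
#' group of reference communities without assuming equal variances between
#' "groups" of size one and many. The observed statistic is the mean
#' unweighted UniFrac distance from the query to each group member. The
#' null distribution resamples reads with replacement from the pooled group
#' counts: each of `B` replicates draws a pseudo-community of `depth` reads
#' (multinomial over the pooled relative abundances) and records its mean
#' UniFrac distance to the group members. Reported are the null mean, the
#' percentile 95% confidence interval, and the one-sided
#' `p = (#{null >= observed} + 1)/(B + 1)`.
#'
#' @param table An [otu_table()] holding the query and group samples.
#' @param tree Rooted phylogeny with branch lengths over the OTUs.
#' @param query_id Sample id of the query community.
#' @param group_ids At least two group sample ids (query excluded).
#' @param B Bootstrap replicates (default 1000).
#' @param depth Reads per pseudo-community; default the query's own depth.
#' @param seed Integer seed.
#' @param conf_level Confidence level for the percentile interval
#'   (default 0.95).
#' @return List of class `bootstrap_test`: `observed_distance`,
#'   `null_mean`, `ci_lower`, `ci_upper`, `conf_level`, `p`, `B`, `depth`,
#'   `seed`, `query_id`, `group_ids`.
#' @export
bootstrap_one_vs_group <- function(table, tree, query_id, group_ids,
                                   B = 1000, depth = NULL, seed = NULL,
                                   conf_level = 0.95) {
  stopifnot(inherits(table, "otu_table"))
  if (query_id %in% group_ids)
    stop("query must not be part of the group", call. = FALSE)
  if (length(group_ids) < 2)
    stop("group needs at least two samples", call. = FALSE)
  m <- unclass_otu(table)
  missing_ids <- setdiff(c(query_id, group_ids), rownames(m))
  if (length(missing_ids) > 0)
    stop("samples not in table: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  pooled <- colSums(m[group_ids, , drop = FALSE])
  if (sum(pooled) == 0) stop("empty pooled group", call. = FALSE)
  depth <- depth %||% sum(m[query_id, ])
  if (depth < 1) stop("query community has zero reads", call. = FALSE)
  use_seed(seed)

  bi <- branch_incidence(tree)
  tips <- tree$tip.label
  w <- bi$lengths
  B_members <- edge_presence_of(bi, m[group_ids, , drop = FALSE], tips)
  b_query <- edge_presence_of(bi, m[query_id, , drop = FALSE], tips)[, 1]
  observed <- mean(unifrac_one_vs_many(b_query, B_members, w))

  probs <- pooled / sum(pooled)
  pseudo <- rmultinom(B, depth, probs)           # taxa x B
  tip_idx <- match(colnames(m), tips)
  Pp <- matrix(FALSE, length(tips), B)
  Pp[tip_idx[!is.na(tip_idx)], ] <- pseudo[!is.na(tip_idx), ] > 0
  Bp <- (bi$incidence %*% Pp) > 0                # edges x B
  s_rep <- colSums(Bp * w)
  s_m <- colSums(B_members * w)
  both <- crossprod(B_members * w, Bp)           # members x B
  uni <- outer(s_m, s_rep, "+") - 2 * both
  tot <- outer(s_m, s_rep, "+") - both
  null_dist <- colMeans(ifelse(tot > 0, uni / tot, 0))

  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(null_dist, c(alpha, 1 - alpha), type = 7))
  p <- (sum(null_dist >= observed - 1e-12) + 1) / (B + 1)
  structure(list(observed_distance = observed,
                 null_mean = mean(null_dist),
                 ci_lower = ci[1], ci_upper = ci[2],
                 conf_level = conf_level, p = p, B = B, depth = depth,
                 seed = seed, query_id = query_id, group_ids = group_ids,
                 null_distribution = null_dist),
            class = "bootstrap_test")
}

#' Render a bootstrap test in the conventional reporting shape
#'
#' `mean (95% CI: lower; upper), observed distance, p`.
#'
#' @param x A `bootstrap_test`.
#' @param ... Unused.
#' @return A single character string.
#' @export
format.bootstrap_test <- function(x, ...) {
  sprintf(paste0("mean UniFrac bootstrapping distance of %.3f (%.0f%% CI: ",
                 "%.3f; %.3f), observed UniFrac distance %.3f, p = %.3g"),
          x$null_mean, 100 * x$conf_level, x$ci_lower, x$ci_upper,
          x$observed_distance, x$p)
}

#' @export
print.bootstrap_test <- function(x, ...) {
  cat("Bootstrap one-vs-group test (", x$query_id, " vs ",
      length(x$group_ids), " samples, B = ", x$B, ")\n  ",
      format(x), "\n", sep = "")
  invisible(x)
}

#' PERMANOVA power against sample size by read resampling
#'
#' For each target per-group size `m`, draws `n_boot` pseudo-studies: each
#' group contributes `m` pseudo-samples resampled read-wise (with
#' replacement, as in [bootstrap_one_vs_group()]) from its pooled counts,
#' a PERMANOVA is run on the unweighted UniFrac distances of each
#' pseudo-study, and power is the fraction of p-values at or below `alpha`.
#'
#' @param table An [otu_table()].
#' @param tree Rooted phylogeny.
#' @param labels Two-level group labels named by (or aligned to) samples.
#' @param group_sizes Integer vector of per-group sizes (each >= 2).
#' @param n_boot Pseudo-studies per size (default 100).
#' @param n_perm Permutations per PERMANOVA (default 199).
#' @param depth Reads per pseudo-sample; default the mean sample depth.
#' @param alpha Rejection level (default 0.05).
#' @param seed Integer seed.
#' @return Data frame: `group_size`, `power`, `n_boot`.
#' @export
permanova_power_curve <- function(table, tree, labels, group_sizes,
                                  n_boot = 100, n_perm = 199, depth = NULL,
                                  alpha = 0.05, seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  if (any(group_sizes < 2)) stop("group sizes must be >= 2", call. = FALSE)
  m <- unclass_otu(table)
  if (!is.null(names(labels))) labels <- labels[rownames(m)]
  groups <- unique(as.character(labels))
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  depth <- depth %||% round(mean(rowSums(m)))
  use_seed(seed)
  pooled <- lapply(groups, function(g)
    colSums(m[labels == g, , drop = FALSE]))
  bi <- branch_incidence(tree)
  tips <- tree$tip.label
  w <- bi$lengths
  tip_idx <- match(colnames(m), tips)
  rows <- lapply(group_sizes, function(gs) {
    rej <- 0L
    for (b in seq_len(n_boot)) {
      pres <- matrix(FALSE, length(tips), 2 * gs)
      lab <- rep(groups, each = gs)
      for (g in 1:2) {
        draw <- rmultinom(gs, depth, pooled[[g]] / sum(pooled[[g]]))
        pres[tip_idx[!is.na(tip_idx)], (g - 1) * gs + seq_len(gs)] <-
          draw[!is.na(tip_idx), ] > 0
      }
      Bm <- (bi$incidence %*% pres) > 0
      s <- colSums(Bm * w)
      both <- crossprod(Bm, Bm * w)
      uni <- outer(s, s, "+") - 2 * both
      tot <- outer(s, s, "+") - both
      d <- ifelse(tot > 0, uni / tot, 0)
      diag(d) <- 0
      dimnames(d) <- list(paste0("ps", seq_len(2 * gs)),
                          paste0("ps", seq_len(2 * gs)))
      res <- permanova(as_distance_matrix((d + t(d)) / 2), lab,
                       n_perm = n_perm)
      if (res$p <= alpha) rej <- rej + 1L
    }
    data.frame(group_size = gs, power = rej / n_boot, n_boot = n_boot)
  })
  do.call(rbind, rows)
}
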
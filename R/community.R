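# prepare labels aligned to a distance matrix; returns list(d, labels)
align_labels <- function(d, labels) {
  d <- as_distance_matrix(d, tol = 1e-8)
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), rownames(d)))
      stop("label names do not match matrix ids", call. = FALSE)
    labels <- labels[rownames(d)]
  } else if (length(labels) != nrow(d)) {
    stop("labels must align with the distance matrix", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("need at least two groups", call. = FALSE)
  if (any(table(labels) < 1)) stop("empty group", call. = FALSE)
  list(d = d, labels = labels)
}

# permutation index set: exhaustive when n! fits in n_perm, else sampled
permutation_set <- function(n, n_perm, seed) {
  exhaustive <- n <= 8 && factorial(n) <= n_perm
  if (exhaustive) {
    list(perms = all_permutations(n), exhaustive = TRUE)
  } else {
    use_seed(seed)
    list(perms = t(replicate(n_perm, sample.int(n))), exhaustive = FALSE)
  }
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance partitioning squared
#' distances between and within groups:
#' `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`,
#' `pseudo-F = (SS_between/df_between) / (SS_within/df_within)` with
#' `df_between = a - 1`, `df_within = N - a`. The p-value permutes raw group
#' labels with the add-one rule `p = (#{F* >= F} + 1)/(n_perm + 1)`; when
#' all `n!` label permutations fit within `n_perm` they are enumerated
#' exhaustively and the p-value is the exact proportion.
#'
#' @param d Symmetric distance matrix.
#' @param labels Group labels aligned to the matrix ids (or named by them).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return List of class `permanova_result`: `pseudo_F`, `R2`,
#'   `df_between`, `df_within`, `p`, `n_permutations`, `exhaustive`,
#'   `ss_between`, `ss_within`, `ss_total`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = NULL) {
  al <- align_labels(d, labels)
  d2 <- al$d^2
  labels <- al$labels
  n <- nrow(d2)
  a <- length(unique(labels))
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within_of <- function(lab) {
    ssw <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ssw
  }
  df_b <- a - 1L
  df_w <- n - a
  f_of <- function(lab) {
    ssw <- ss_within_of(lab)
    ((ss_total - ssw) / df_b) / (ssw / df_w)
  }
  f_obs <- f_of(labels)
  ps <- permutation_set(n, n_perm, seed)
  f_perm <- apply(ps$perms, 1L, function(ix) f_of(labels[ix]))
  p <- perm_pvalue(f_obs, f_perm, ps$exhaustive, "greater")
  ssw <- ss_within_of(labels)
  structure(list(pseudo_F = f_obs, R2 = (ss_total - ssw) / ss_total,
                 df_between = df_b, df_within = df_w, p = p,
                 n_permutations = nrow(ps$perms),
                 exhaustive = ps$exhaustive,
                 ss_between = ss_total - ssw, ss_within = ssw,
                 ss_total = ss_total),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d,%d) = %.4g, R2 = %.3f, p = %.4g (%s%d permutations)\n",
              x$df_between, x$df_within, x$pseudo_F, x$R2, x$p,
              if (x$exhaustive) "exhaustive " else "", x$n_permutations))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all `N(N-1)/2` distances (mid-ranks for ties) and contrasts mean
#' between-group and within-group ranks:
#' `R = (mean_rank_between - mean_rank_within) / (M/2)`, `M = N(N-1)/2`.
#' Permutation p-value as in [permanova()].
#'
#' @inheritParams permanova
#' @return List of class `anosim_result`: `R`, `p`, `n_permutations`,
#'   `exhaustive`.
#' @export
anosim_test <- function(d, labels, n_perm = 999, seed = NULL) {
  al <- align_labels(d, labels)
  labels <- al$labels
  n <- nrow(al$d)
  lt <- lower.tri(al$d)
  rk <- rank(al$d[lt])
  m_half <- (n * (n - 1) / 2) / 2
  pair_i <- row(al$d)[lt]
  pair_j <- col(al$d)[lt]
  r_of <- function(lab) {
    between <- lab[pair_i] != lab[pair_j]
    (mean(rk[between]) - mean(rk[!between])) / m_half
  }
  r_obs <- r_of(labels)
  ps <- permutation_set(n, n_perm, seed)
  r_perm <- apply(ps$perms, 1L, function(ix) r_of(labels[ix]))
  p <- perm_pvalue(r_obs, r_perm, ps$exhaustive, "greater")
  structure(list(R = r_obs, p = p, n_permutations = nrow(ps$perms),
                 exhaustive = ps$exhaustive),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4g, p = %.4g (%d permutations)\n",
              x$R, x$p, x$n_permutations))
  invisible(x)
}

#' Homogeneity of multivariate dispersions
#'
#' Embeds the distance matrix by principal coordinates (Cailliez-corrected
#' by default so the embedding is complete), computes each sample's distance
#' to its group centroid, and tests equality of mean dispersion with a
#' one-way ANOVA F whose p-value is obtained by permuting group labels over
#' the fixed centroid distances.
#'
#' @inheritParams permanova
#' @param correction Distance-matrix correction passed to
#'   [principal_coordinates()] (default `"cailliez"`).
#' @return List of class `dispersion_result`: `F`, `df1`, `df2`, `p`,
#'   `distances` (to centroids), `n_permutations`.
#' @export
dispersion_test <- function(d, labels, n_perm = 999, seed = NULL,
                            correction = "cailliez") {
  al <- align_labels(d, labels)
  labels <- al$labels
  if (any(table(labels) < 2))
    warning("groups of size 1 contribute no within-group dispersion")
  pc <- principal_coordinates(al$d, correction = correction)
  co <- pc$coordinates
  z <- numeric(nrow(co))
  for (g in unique(labels)) {
    idx <- which(labels == g)
    cen <- colMeans(co[idx, , drop = FALSE])
    z[idx] <- sqrt(rowSums((co[idx, , drop = FALSE] -
                              rep(cen, each = length(idx)))^2))
  }
  a <- length(unique(labels))
  n <- length(z)
  f_of <- function(lab) {
    gm <- mean(z)
    ssb <- 0; ssw <- 0
    for (g in unique(lab)) {
      zi <- z[lab == g]
      ssb <- ssb + length(zi) * (mean(zi) - gm)^2
      ssw <- ssw + sum((zi - mean(zi))^2)
    }
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(labels)
  ps <- permutation_set(n, n_perm, seed)
  f_perm <- apply(ps$perms, 1L, function(ix) f_of(labels[ix]))
  p <- perm_pvalue(f_obs, f_perm, ps$exhaustive, "greater")
  structure(list(F = f_obs, df1 = a - 1L, df2 = n - a, p = p,
                 distances = setNames(z, rownames(al$d)),
                 n_permutations = nrow(ps$perms)),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("Dispersion homogeneity: F = %.4g, d.f. = %d, p = %.4g\n",
              x$F, x$df1, x$p))
  invisible(x)
}

#' Core microbiome
#'
#' OTUs present (count > 0) in at least `ceil(min_fraction * n_samples)`
#' samples, sorted. With nine samples and the conventional fraction 0.77
#' this resolves to presence in at least seven samples.
#'
#' @param table An [otu_table()].
#' @param min_fraction Prevalence fraction in (0, 1] (default 0.77).
#' @return Sorted character vector of core OTU ids.
#' @export
core_microbiome <- function(table, min_fraction = 0.77) {
  stopifnot(inherits(table, "otu_table"))
  if (nrow(table) == 0) stop("empty table", call. = FALSE)
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1]", call. = FALSE)
  m <- unclass_otu(table)
  threshold <- ceiling(min_fraction * nrow(m))
  prev <- colSums(m > 0)
  sort(colnames(m)[prev >= threshold])
}

#' Differential features between two groups (Welch + BH)
#'
#' Per feature: Welch's two-sample t-test (unequal sample sizes and
#' variances, two-sided), Benjamini-Hochberg adjustment across features,
#' and a practical-effect filter on the absolute difference of group means.
#' Only features present in both groups are compared.
#'
#' @param relabund Numeric matrix (samples x features) of relative
#'   abundances / relative gene copies.
#' @param group_labels Two-level group label per sample (named by sample or
#'   aligned).
#' @param fdr_level BH-adjusted significance threshold (default 0.05).
#' @param min_mean_diff Minimum absolute difference of group means on the
#'   relative scale (default 0.05, i.e. >5 percentage points).
#' @return Data frame: `feature`, `mean_1`, `mean_2`, `mean_diff`, `t`,
#'   `df`, `p`, `p_adjusted`, `significant`; attribute `groups` records the
#'   two group names.
#' @export
differential_features <- function(relabund, group_labels, fdr_level = 0.05,
                                  min_mean_diff = 0.05) {
  relabund <- as.matrix(relabund)
  if (!is.null(names(group_labels)))
    group_labels <- group_labels[rownames(relabund)]
  groups <- unique(as.character(group_labels))
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  i1 <- which(group_labels == groups[1])
  i2 <- which(group_labels == groups[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("each group needs >= 2 samples for Welch's test", call. = FALSE)
  present <- colSums(relabund[i1, , drop = FALSE] > 0) > 0 &
    colSums(relabund[i2, , drop = FALSE] > 0) > 0
  feats <- colnames(relabund)[present]
  res <- lapply(feats, function(f) {
    x <- relabund[i1, f]; y <- relabund[i2, f]
    if (var(x) == 0 && var(y) == 0) {
      data.frame(feature = f, mean_1 = mean(x), mean_2 = mean(y),
                 mean_diff = mean(x) - mean(y), t = 0, df = NA_real_,
                 p = 1, stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      data.frame(feature = f, mean_1 = mean(x), mean_2 = mean(y),
                 mean_diff = mean(x) - mean(y),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adjusted < fdr_level &
    abs(out$mean_diff) > min_mean_diff
  attr(out, "groups") <- groups
  out[order(out$p_adjusted), ]
}
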
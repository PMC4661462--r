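#' Mantel test between two distance matrices
#'
#' `r` is the Pearson correlation of the `n(n-1)/2` lower-triangle entries.
#' The null permutes rows and columns of the first matrix simultaneously;
#' the one-sided p-value uses the add-one rule, or the exact proportion
#' when all `n!` permutations are enumerated (automatic for small `n`).
#'
#' @param a,b Symmetric distance matrices over the same ids.
#' @param n_perm Number of permutations (default 999).
#' @param tail `"greater"` (default) or `"less"`.
#' @param seed Integer seed.
#' @return List of class `mantel_result`: `r`, `p`, `n_permutations`,
#'   `tail`, `exhaustive`.
#' @export
mantel_test <- function(a, b, n_perm = 999, tail = c("greater", "less"),
                        seed = NULL) {
  tail <- match.arg(tail)
  a <- as_distance_matrix(a, tol = 1e-8)
  b <- check_same_ids(a, as_distance_matrix(b, tol = 1e-8))
  n <- nrow(a)
  if (n < 4) stop("need at least 4 objects", call. = FALSE)
  lt <- lower.tri(a)
  bv <- b[lt]
  if (sd(a[lt]) == 0 || sd(bv) == 0)
    stop("constant distance matrix: correlation undefined", call. = FALSE)
  r_obs <- cor(a[lt], bv)
  ps <- permutation_set(n, n_perm, seed)
  r_perm <- apply(ps$perms, 1L, function(ix) cor(a[ix, ix][lt], bv))
  p <- perm_pvalue(r_obs, r_perm, ps$exhaustive, tail)
  structure(list(r = r_obs, p = p, n_permutations = nrow(ps$perms),
                 tail = tail, exhaustive = ps$exhaustive),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4g, p = %.4g (one-sided %s, %d permutations)\n",
              x$r, x$p, x$tail, x$n_permutations))
  invisible(x)
}

# first-order partial correlation from the three pairwise correlations;
# the 0/0 case (e.g. b identical to the control) is the algebraic zero
partial_r <- function(r_ab, r_ac, r_bc) {
  num <- r_ab - r_ac * r_bc
  den <- sqrt(pmax((1 - r_ac^2) * (1 - r_bc^2), 0))
  if (den < 1e-12) {
    if (abs(num) < 1e-12) return(0)
    stop("degenerate partial correlation: |r| = 1 with the control matrix",
         call. = FALSE)
  }
  num / den
}

#' Partial Mantel test
#'
#' Correlation of `a` and `b` controlling for `c`, via the first-order
#' partial correlation
#' `r_ab.c = (r_ab - r_ac r_bc) / sqrt((1 - r_ac^2)(1 - r_bc^2))` on
#' lower-triangle entries. The null permutes `a` only (simple permutation
#' scheme), recomputing the partial correlation each time.
#'
#' @param a,b,c Symmetric distance matrices over the same ids (`c` is the
#'   control).
#' @inheritParams mantel_test
#' @return List of class `mantel_result` with the partial `r`.
#' @export
partial_mantel_test <- function(a, b, c, n_perm = 999,
                                tail = c("greater", "less"), seed = NULL) {
  tail <- match.arg(tail)
  a <- as_distance_matrix(a, tol = 1e-8)
  b <- check_same_ids(a, as_distance_matrix(b, tol = 1e-8))
  c <- check_same_ids(a, as_distance_matrix(c, tol = 1e-8))
  n <- nrow(a)
  if (n < 4) stop("need at least 4 objects", call. = FALSE)
  lt <- lower.tri(a)
  bv <- b[lt]; cv <- c[lt]
  if (sd(a[lt]) == 0 || sd(bv) == 0 || sd(cv) == 0)
    stop("constant distance matrix: correlation undefined", call. = FALSE)
  r_bc <- cor(bv, cv)
  r_obs <- partial_r(cor(a[lt], bv), cor(a[lt], cv), r_bc)
  ps <- permutation_set(n, n_perm, seed)
  r_perm <- apply(ps$perms, 1L, function(ix) {
    av <- a[ix, ix][lt]
    partial_r(cor(av, bv), cor(av, cv), r_bc)
  })
  p <- perm_pvalue(r_obs, r_perm, ps$exhaustive, tail)
  structure(list(r = r_obs, p = p, n_permutations = nrow(ps$perms),
                 tail = tail, exhaustive = ps$exhaustive),
            class = "mantel_result")
}

#' Slope stability under pairwise-comparison subsampling
#'
#' Diagnoses whether the slope of a distance-distance relationship is
#' stable given the number of samples: for `k = 0 ... max_removed`, draws
#' `n_draws` random subsets of `n - k` samples and refits the ordinary
#' least-squares slope of response on predictor over the remaining
#' lower-triangle pairs. A slope whose spread stays small as samples are
#' removed has converged.
#'
#' @param response_d,predictor_d Symmetric distance matrices over the same
#'   ids.
#' @param max_removed Largest number of samples removed (`<= n - 3`).
#' @param n_draws Subsets per removal count (default 100; `k = 0` always
#'   contributes the single full-data slope).
#' @param seed Integer seed.
#' @return List of class `slope_convergence`: `slopes` (list indexed by
#'   `k`), `summary` (data frame `k`, `n_draws`, `mean`, `sd`), `seed`.
#' @export
slope_convergence <- function(response_d, predictor_d, max_removed,
                              n_draws = 100, seed = NULL) {
  a <- as_distance_matrix(response_d, tol = 1e-8)
  b <- check_same_ids(a, as_distance_matrix(predictor_d, tol = 1e-8))
  n <- nrow(a)
  if (max_removed > n - 3)
    stop("max_removed must leave at least 3 samples", call. = FALSE)
  use_seed(seed)
  slope_of <- function(idx) {
    lt <- lower.tri(a[idx, idx])
    x <- b[idx, idx][lt]; y <- a[idx, idx][lt]
    if (sd(x) == 0) stop("constant predictor in subset", call. = FALSE)
    cov(x, y) / var(x)
  }
  slopes <- list()
  for (k in 0:max_removed) {
    if (k == 0) {
      slopes[["0"]] <- slope_of(seq_len(n))
    } else {
      slopes[[as.character(k)]] <- vapply(seq_len(n_draws), function(d)
        slope_of(sample.int(n, n - k)), numeric(1))
    }
  }
  summary <- data.frame(
    k = 0:max_removed,
    n_draws = c(1L, rep(n_draws, max_removed)),
    mean = vapply(slopes, mean, numeric(1)),
    sd = vapply(slopes, function(s) if (length(s) > 1) sd(s) else 0,
                numeric(1)))
  structure(list(slopes = slopes, summary = summary, seed = seed),
            class = "slope_convergence")
}
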
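#' Jost's D ("actual differentiation") between populations
#'
#' Allele-frequency differentiation robust to within-population diversity,
#' unlike F_ST-style measures which shrink as heterozygosity rises. For a
#' population pair and one locus: the within-population heterozygosity
#' estimate uses the Nei-Chesson small-sample correction
#' `H_S = (2N'/(2N'-1)) (1 - mean_i sum p_i^2)` with `N'` the harmonic
#' mean sample size of the pair; the total-heterozygosity estimate from
#' the pair's mean allele frequencies carries the matching correction
#' `H_T = (1 - sum pbar^2) + H_S/(2 N' n)`; and
#' `D = ((H_T - H_S) / (1 - H_S)) * n/(n-1)` with `n = 2` populations.
#' Without the `H_T` correction the estimator is biased upward at small
#' sample sizes, so that null populations would show spurious
#' differentiation.
#' The multi-locus D applies the same formula to across-locus means of
#' `H_S` and `H_T` (rather than averaging per-locus D values); per-locus
#' values are also reported. A monomorphic locus pair contributes `D = 0`.
#'
#' @param genotypes A [genotype_table()] with at least two populations of
#'   at least two scored individuals each.
#' @param clamp_negative Clamp small negative sampling-noise estimates to 0
#'   (default `TRUE`; raw values kept in `pairwise_raw`).
#' @return List of class `dest_result`: `pairwise` (populations x
#'   populations matrix of multi-locus D), `pairwise_raw` (unclamped),
#'   `per_locus` (list of per-locus pairwise matrices), `h_components`
#'   (data frame of per-pair per-locus `H_S`, `H_T`), `populations`.
#' @export
jost_dest <- function(genotypes, clamp_negative = TRUE) {
  stopifnot(inherits(genotypes, "genotype_table"))
  pops <- unique(genotypes$population)
  if (length(pops) < 2)
    stop("need at least two populations", call. = FALSE)
  af <- allele_frequencies(genotypes)
  loci <- names(af)
  for (p in pops) {
    n_scored <- vapply(loci, function(l) af[[l]][[p]]$n, numeric(1))
    if (all(n_scored < 2))
      stop("population ", p, " has fewer than two scored individuals",
           call. = FALSE)
  }
  np <- length(pops)
  d_raw <- matrix(0, np, np, dimnames = list(pops, pops))
  per_locus <- lapply(loci, function(l)
    matrix(0, np, np, dimnames = list(pops, pops)))
  names(per_locus) <- loci
  hrows <- list()
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    hs_l <- numeric(0); ht_l <- numeric(0)
    for (l in loci) {
      fi <- af[[l]][[pops[i]]]; fj <- af[[l]][[pops[j]]]
      if (fi$n < 2 || fj$n < 2) next
      alleles <- union(names(fi$freq), names(fj$freq))
      pi_ <- as.numeric(fi$freq[alleles]); pi_[is.na(pi_)] <- 0
      pj_ <- as.numeric(fj$freq[alleles]); pj_[is.na(pj_)] <- 0
      n_harm <- 2 / (1 / fi$n + 1 / fj$n)
      hs_obs <- ((1 - sum(pi_^2)) + (1 - sum(pj_^2))) / 2
      hs <- (2 * n_harm / (2 * n_harm - 1)) * hs_obs
      pbar <- (pi_ + pj_) / 2
      ht <- (1 - sum(pbar^2)) + hs / (2 * n_harm * 2)
      hs_l <- c(hs_l, hs); ht_l <- c(ht_l, ht)
      d_locus <- if (ht <= 0 && hs <= 0) 0
                 else ((ht - hs) / (1 - hs)) * 2
      per_locus[[l]][i, j] <- per_locus[[l]][j, i] <- d_locus
      hrows[[length(hrows) + 1L]] <- data.frame(
        pop_1 = pops[i], pop_2 = pops[j], locus = l, h_s = hs, h_t = ht,
        stringsAsFactors = FALSE)
    }
    if (length(hs_l) == 0)
      stop("no locus scored in both populations ", pops[i], " and ",
           pops[j], call. = FALSE)
    mhs <- mean(hs_l); mht <- mean(ht_l)
    d_raw[i, j] <- d_raw[j, i] <-
      if (mht <= 0 && mhs <= 0) 0 else ((mht - mhs) / (1 - mhs)) * 2
  }
  d <- if (clamp_negative) pmax(d_raw, 0) else d_raw
  structure(list(pairwise = d, pairwise_raw = d_raw,
                 per_locus = per_locus,
                 h_components = do.call(rbind, hrows),
                 populations = pops),
            class = "dest_result")
}

#' @export
print.dest_result <- function(x, ...) {
  cat("Jost's D over", length(x$populations), "populations;",
      "mean pairwise D =", format(mean(lower_tri(x$pairwise)), digits = 3),
      "\n")
  invisible(x)
}
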
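# shared internal helpers

lower_tri <- function(m) m[lower.tri(m)]

#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline consumes its own sub-seed, derived
#' deterministically from the master seed and a stage label, so changing one
#' stage's settings never perturbs another stage's random stream.
#'
#' @param seed Master integer seed.
#' @param label Character stage label.
#' @return An integer seed below 2^31.
#' @export
sub_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(seed) %% 20000000 * 104729 + h) %% 2147483647)
}

# all n! permutations of 1..n as an (n! x n) integer matrix; used for the
# exhaustive-enumeration switch of the permutation tests (n <= 8)
all_permutations <- function(n) {
  stopifnot(n >= 1L, n <= 8L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  blocks <- vector("list", n)
  for (k in seq_len(n)) {
    m <- matrix(0L, nrow(sub), n)
    m[, k] <- n
    m[, setdiff(seq_len(n), k)] <- sub
    blocks[[k]] <- m
  }
  do.call(rbind, blocks)
}

# validate a square symmetric hollow distance matrix; symmetrize tiny
# asymmetries (<= tol) by averaging, error otherwise
as_distance_matrix <- function(d, tol = 1e-8, what = "distance matrix") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop(what, " must be square", call. = FALSE)
  if (is.null(rownames(d))) rownames(d) <- colnames(d)
  if (is.null(colnames(d))) colnames(d) <- rownames(d)
  if (is.null(rownames(d))) {
    ids <- paste0("s", seq_len(nrow(d)))
    dimnames(d) <- list(ids, ids)
  }
  if (!identical(rownames(d), colnames(d)))
    stop(what, ": row and column ids differ", call. = FALSE)
  if (anyDuplicated(rownames(d))) stop(what, ": duplicate ids", call. = FALSE)
  if (any(!is.finite(d))) stop(what, ": non-finite entries", call. = FALSE)
  if (any(d < 0)) stop(what, ": negative entries", call. = FALSE)
  asym <- max(abs(d - t(d)))
  if (asym > tol)
    stop(what, ": asymmetric beyond tolerance (max |d_ij - d_ji| = ",
         format(asym), ")", call. = FALSE)
  d <- (d + t(d)) / 2
  if (any(diag(d) != 0))
    stop(what, ": diagonal must be exactly zero", call. = FALSE)
  d
}

# align a second matrix (or labels) to the id order of the first
check_same_ids <- function(a, b, what = "matrices") {
  if (!setequal(rownames(a), rownames(b)))
    stop(what, " must share the same ids", call. = FALSE)
  b[rownames(a), rownames(a)]
}

# one-sided permutation p-value; add-one rule for sampled permutations,
# plain proportion (identity included in the set) for exhaustive ones
perm_pvalue <- function(stat_obs, stat_perm, exhaustive,
                        tail = c("greater", "less")) {
  tail <- match.arg(tail)
  eps <- 1e-12
  hits <- if (tail == "greater") sum(stat_perm >= stat_obs - eps)
          else sum(stat_perm <= stat_obs + eps)
  if (exhaustive) hits / length(stat_perm)
  else (hits + 1) / (length(stat_perm) + 1)
}

# seed the RNG for the calling function only: the previous global stream
# is restored when the caller exits, so seeded calls are deterministic
# without perturbing the ambient randomness of loops around them
use_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  expr <- bquote(assign(".Random.seed", .(old), envir = globalenv()))
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  set.seed(seed)
  invisible(NULL)
}

rdirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
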
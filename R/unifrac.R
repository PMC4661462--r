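# Branch x tip incidence: logical matrix with one row per edge, one column
# per tip, TRUE when the edge lies on the path from the root to that tip.
# All phylogenetic diversity computations reduce to sums over this matrix.
branch_incidence <- function(tree) {
  validate_phylogeny(tree)
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  edge <- tree$edge
  po <- edge[ape::postorder(tree), , drop = FALSE]
  below <- matrix(FALSE, nn, nt)
  below[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (k in seq_len(nrow(po))) {
    parent <- po[k, 1]; child <- po[k, 2]
    below[parent, ] <- below[parent, ] | below[child, ]
  }
  inc <- below[edge[, 2], , drop = FALSE]
  colnames(inc) <- tree$tip.label
  list(incidence = inc, lengths = tree$edge.length)
}

# branch presence matrix (edges x communities) for a presence/absence
# community matrix P (communities x tips, in tree tip order)
branch_presence <- function(bi, presence) {
  (bi$incidence %*% t(presence)) > 0
}

#' UniFrac distances between communities
#'
#' Unweighted UniFrac between two communities is the branch length unique to
#' either community divided by the total branch length covered by their
#' union; it uses presence/absence only, which is the variant most
#' informative when communities differ primarily in which taxa can live in
#' them. The normalized weighted variant, which weights branches by the
#' difference in the relative read mass descending from them, is offered for
#' abundance-driven contrasts.
#'
#' @param table An [otu_table()]; every OTU with a positive count must be a
#'   tip of `tree`.
#' @param tree Rooted phylogeny with branch lengths over the OTUs.
#' @param weighted If `TRUE`, normalized weighted UniFrac; default unweighted.
#' @param rarefy_depth Optional common depth: when given, every sample is
#'   rarefied to it (without replacement) before distances are computed.
#'   Default `NULL` uses the raw counts.
#' @param seed Seed for the optional rarefaction.
#' @return Symmetric distance matrix over samples.
#' @export
unifrac <- function(table, tree, weighted = FALSE, rarefy_depth = NULL,
                    seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  m <- unclass_otu(table)
  if (!is.null(rarefy_depth)) {
    use_seed(seed)
    m <- t(apply(m, 1, rarefy_counts, depth = rarefy_depth))
  }
  present_otus <- colnames(m)[colSums(m) > 0]
  missing_tips <- setdiff(present_otus, tree$tip.label)
  if (length(missing_tips) > 0)
    stop("OTUs absent from the tree: ",
         paste(utils::head(missing_tips, 5), collapse = ", "), call. = FALSE)
  if (any(rowSums(m) == 0))
    stop("UniFrac undefined for a community with zero taxa: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "), call. = FALSE)
  bi <- branch_incidence(tree)
  # align community matrix to tip order (tips without counts get zeros)
  P <- matrix(0, nrow(m), length(tree$tip.label),
              dimnames = list(rownames(m), tree$tip.label))
  P[, intersect(colnames(m), tree$tip.label)] <-
    m[, intersect(colnames(m), tree$tip.label)]
  w <- bi$lengths
  if (!weighted) {
    B <- branch_presence(bi, P > 0)        # edges x samples
    s <- colSums(B * w)                    # covered branch length per sample
    both <- crossprod(B, B * w)            # shared branch length
    uni <- outer(s, s, "+") - 2 * both
    tot <- outer(s, s, "+") - both
    d <- ifelse(tot > 0, uni / tot, 0)
  } else {
    prop <- P / rowSums(P)
    A <- bi$incidence %*% t(prop)          # mass below each edge per sample
    n <- ncol(A)
    d <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      num <- sum(w * abs(A[, i] - A[, j]))
      den <- sum(w * (A[, i] + A[, j]))
      d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
    }
    dimnames(d) <- list(colnames(A), colnames(A))
  }
  diag(d) <- 0
  as_distance_matrix(d, tol = 1e-12, what = "UniFrac matrix")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres `-D^2/2`, eigendecomposes, and returns coordinates scaled
#' by the square root of each positive eigenvalue. All eigenvalues are
#' reported, including negative ones arising from non-Euclidean distances;
#' axes with eigenvalue below `eps` are dropped from the coordinates (no
#' correction by default). The Cailliez correction, which adds the smallest
#' constant to off-diagonal distances making the configuration Euclidean, is
#' available for procedures that need a full embedding (e.g. the dispersion
#' test).
#'
#' @param d Symmetric distance matrix.
#' @param correction `"none"` (default) or `"cailliez"`.
#' @param eps Eigenvalue retention threshold (default `1e-10`).
#' @return List with `coordinates` (n x k), `eigenvalues` (all n),
#'   and `correction_constant`.
#' @export
principal_coordinates <- function(d, correction = c("none", "cailliez"),
                                  eps = 1e-10) {
  correction <- match.arg(correction)
  d <- as_distance_matrix(d, tol = 1e-8)
  n <- nrow(d)
  if (n < 2) stop("need at least two objects", call. = FALSE)
  cc <- 0
  if (correction == "cailliez") {
    cc <- cailliez_constant(d)
    if (cc > 0) {
      d <- d + cc
      diag(d) <- 0
    }
  }
  G <- double_centre(-0.5 * d^2)
  eg <- eigen(G, symmetric = TRUE)
  ev <- eg$values
  keep <- which(ev > eps)
  coords <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(ev[keep]), length(keep))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_along(keep))
  list(coordinates = coords, eigenvalues = ev, correction_constant = cc)
}

double_centre <- function(m) {
  rm <- rowMeans(m); cm <- colMeans(m); gm <- mean(m)
  m - outer(rm, rep(1, ncol(m))) - outer(rep(1, nrow(m)), cm) + gm
}

# smallest constant c such that d + c (off-diagonal) has a Euclidean
# representation: largest real eigenvalue of the standard companion matrix
cailliez_constant <- function(d) {
  n <- nrow(d)
  d1 <- double_centre(-0.5 * d^2)
  d2 <- double_centre(-0.5 * d)
  M <- rbind(cbind(matrix(0, n, n), 2 * d1),
             cbind(-diag(n), -4 * d2))
  ev <- eigen(M, only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8]), 0)
}
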
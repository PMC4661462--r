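# Independent brute-force oracles and small fixture builders. These are
# deliberately naive re-derivations (path walks, pair loops, step-up loops)
# kept separate from the package's vectorized implementations.

oracle_chao1 <- function(counts, bias_corrected = TRUE) {
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1); f2 <- sum(counts == 2)
  if (bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else if (f2 == 0) s_obs + f1 * (f1 - 1) / 2 else s_obs + f1^2 / (2 * f2)
}

# Faith's PD by walking each present tip's path up to the root
oracle_pd <- function(tree, present) {
  if (length(present) == 0) return(0)
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  used <- rep(FALSE, nrow(tree$edge))
  for (tip in match(present, tree$tip.label)) {
    node <- tip
    repeat {
      e <- which(child == node)
      if (length(e) == 0) break
      used[e] <- TRUE
      node <- parent[e]
    }
  }
  sum(tree$edge.length[used])
}

oracle_tips_below <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, oracle_tips_below, tree = tree))
}

# unweighted UniFrac by per-branch enumeration
oracle_unifrac <- function(tree, a, b) {
  uni <- 0; tot <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tb <- oracle_tips_below(tree, tree$edge[e, 2])
    ina <- any(tb %in% a); inb <- any(tb %in% b)
    if (ina || inb) tot <- tot + tree$edge.length[e]
    if (xor(ina, inb)) uni <- uni + tree$edge.length[e]
  }
  if (tot == 0) 0 else uni / tot
}

# Kendall tau-b by explicit pair loops
oracle_kendall_tau <- function(x, y) {
  n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Benjamini-Hochberg step-up, from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1)
    adj_sorted[i] <- min(adj_sorted[i], adj_sorted[i + 1])
  pmin(adj_sorted, 1)[order(o)]
}

# all permutations by simple recursive selection (independent of the
# package's insertion-based enumerator)
oracle_perms <- function(v) {
  if (length(v) <= 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], oracle_perms(v[-i])))
  out
}

oracle_exact_mantel_p <- function(a, b, tail = "greater") {
  lt <- lower.tri(a)
  r_obs <- cor(a[lt], b[lt])
  pm <- oracle_perms(seq_len(nrow(a)))
  rs <- apply(pm, 1, function(ix) cor(a[ix, ix][lt], b[lt]))
  if (tail == "greater") mean(rs >= r_obs - 1e-12)
  else mean(rs <= r_obs + 1e-12)
}

oracle_exact_permanova_p <- function(d, labels) {
  d2 <- d^2; n <- nrow(d)
  a <- length(unique(labels))
  ss_tot <- sum(d2[lower.tri(d2)]) / n
  f_of <- function(lab) {
    ssw <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ((ss_tot - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(labels)
  pm <- oracle_perms(seq_len(n))
  fs <- apply(pm, 1, function(ix) f_of(labels[ix]))
  mean(fs >= f_obs - 1e-12)
}

# labelled symmetric matrix from points
dm_of_points <- function(x) {
  d <- as.matrix(dist(x))
  ids <- paste0("s", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  d
}

# random small community table + matching tree
random_tree_instance <- function(n_tips) {
  tree <- ape::rtree(n_tips)
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree
}

random_presence <- function(tips) {
  k <- sample(seq_along(tips), 1)
  sample(tips, k)
}
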
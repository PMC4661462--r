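test_that("Mantel r honors Pearson identities and affine invariance", {
  set.seed(1)
  a <- dm_of_points(matrix(rnorm(18), 6, 3))
  expect_equal(mantel_test(a, a, n_perm = 99, seed = 1)$r, 1)
  b <- 2 - 0.5 * a; diag(b) <- 0
  expect_equal(mantel_test(a, b, n_perm = 99, seed = 1)$r, -1)
  # separate positive affine transforms leave r unchanged
  b2 <- dm_of_points(matrix(rnorm(18), 6, 3))
  r0 <- mantel_test(a, b2, n_perm = 99, seed = 1)$r
  a2 <- 3 * a + 0.1; diag(a2) <- 0
  b3 <- 0.7 * b2 + 2; diag(b3) <- 0
  expect_equal(mantel_test(a2, b3, n_perm = 99, seed = 1)$r, r0)
  cm <- matrix(1, 6, 6); diag(cm) <- 0; dimnames(cm) <- dimnames(a)
  expect_error(mantel_test(a, cm), "constant")
})

test_that("small-n Mantel p equals the exhaustively enumerated p", {
  set.seed(2)
  for (i in 1:5) {
    a <- dm_of_points(rnorm(5)); b <- dm_of_points(rnorm(5))
    res <- mantel_test(a, b, n_perm = 999, seed = 1)
    expect_true(res$exhaustive)
    expect_equal(res$p, oracle_exact_mantel_p(a, b), tolerance = 1e-12)
    expect_gt(res$p, 0)
  }
})

test_that("partial Mantel matches its closed form and algebraic limits", {
  set.seed(3)
  a <- dm_of_points(matrix(rnorm(24), 8, 3))
  b <- dm_of_points(matrix(rnorm(24), 8, 3))
  cc <- dm_of_points(matrix(rnorm(24), 8, 3))
  res <- partial_mantel_test(a, b, cc, n_perm = 99, seed = 1)
  # closed form vs residual-regression route
  lt <- lower.tri(a)
  ra <- resid(lm(a[lt] ~ cc[lt])); rb <- resid(lm(b[lt] ~ cc[lt]))
  expect_equal(res$r, cor(ra, rb), tolerance = 1e-12)
  # b as its own control: partial correlation is exactly zero
  expect_equal(partial_mantel_test(a, b, b, n_perm = 99, seed = 1)$r, 0,
               tolerance = 1e-12)
  # an uninformative (pure noise) control leaves the correlation almost
  # untouched once there are enough pairs for its spurious r to vanish
  set.seed(4)
  n <- 25
  a2 <- dm_of_points(matrix(rnorm(3 * n), n, 3))
  b2 <- dm_of_points(matrix(rnorm(3 * n), n, 3))
  noise <- matrix(rnorm(n * n, 0, 1e-6), n, n)
  noise <- abs(noise + t(noise)); diag(noise) <- 0
  cn <- 1 + noise; diag(cn) <- 0; dimnames(cn) <- dimnames(a2)
  expect_lt(abs(partial_mantel_test(a2, b2, cn, n_perm = 9, seed = 1)$r -
                  mantel_test(a2, b2, n_perm = 9, seed = 1)$r), 0.02)
})

test_that("flow-corrected river distances decompose up/downstream travel", {
  # linear river: A upstream of B, 10 km
  nodes <- data.frame(node_id = c("A", "B"), latitude = 0, longitude = 0,
                      elevation_m = c(100, 50))
  edges <- data.frame(from = "A", to = "B", length_km = 10)
  locs <- data.frame(location_id = c("up", "down"), node_id = c("A", "B"))
  net <- river_network(nodes, edges, locs)
  expect_equal(corrected_geo_distance(net, lambda_up = 1)["up", "down"], 10)
  expect_equal(corrected_geo_distance(net, lambda_up = 2)["up", "down"], 15)
  # Y confluence: two tributaries T1 (4 km), T2 (6 km) joining at J,
  # travel T1 -> T2 goes 4 km down then 6 km up
  nodes2 <- data.frame(node_id = c("T1", "T2", "J", "M"),
                       latitude = 0, longitude = 0,
                       elevation_m = c(80, 90, 60, 40))
  edges2 <- data.frame(from = c("T1", "T2", "J"), to = c("J", "J", "M"),
                       length_km = c(4, 6, 5))
  locs2 <- data.frame(location_id = c("t1", "t2", "m"),
                      node_id = c("T1", "T2", "M"))
  net2 <- river_network(nodes2, edges2, locs2)
  lam <- 3
  d <- corrected_geo_distance(net2, lambda_up = lam)
  # t1 -> t2: 4 down + 6 up = 4 + 18; t2 -> t1: 6 + 12; mean = 20
  expect_equal(d["t1", "t2"], ((4 + lam * 6) + (6 + lam * 4)) / 2)
  # t1 -> m: all downstream 9; m -> t1: all upstream 27; mean 18
  expect_equal(d["t1", "m"], (9 + lam * 9) / 2)
  expect_error(corrected_geo_distance(net2, locations = c("t1", "zz")),
               "not mapped")
  expect_error(corrected_geo_distance(net2, lambda_up = 0.5), "lambda_up")
  # disconnected pair errors
  nodes3 <- rbind(nodes2, data.frame(node_id = "X", latitude = 0,
                                     longitude = 0, elevation_m = 10))
  locs3 <- rbind(locs2, data.frame(location_id = "x", node_id = "X"))
  net3 <- river_network(nodes3, edges2, locs3)
  expect_error(corrected_geo_distance(net3), "not connected")
  # cycles are rejected at construction
  edges_cyc <- rbind(edges2, data.frame(from = "M", to = "T1",
                                        length_km = 1))
  expect_error(river_network(nodes2, edges_cyc, locs2), "cycles")
})

test_that("Jost's D matches hand-computed heterozygosity cases", {
  # identical realized frequencies: raw D slightly negative, clamped to 0
  g_same <- genotype_table(
    rep(c("p1", "p2"), each = 4), paste0("i", 1:8),
    data.frame(L1 = rep(c("100/100", "100/104", "104/104", "100/104"), 2)))
  res <- jost_dest(g_same)
  expect_equal(res$pairwise[1, 2], 0)
  expect_lte(res$pairwise_raw[1, 2], 0)
  # fixed different alleles: D = 1
  g_fix <- genotype_table(
    rep(c("p1", "p2"), each = 3), paste0("i", 1:6),
    data.frame(L1 = c(rep("100/100", 3), rep("104/104", 3))))
  expect_equal(jost_dest(g_fix)$pairwise[1, 2], 1)
  # 0.7/0.3 vs 0.3/0.7 at N = 5: direct-formula oracle
  mk <- function(p, N) {
    nA <- round(2 * N * p)
    c(rep("100/100", nA %/% 2), rep("100/104", nA %% 2),
      rep("104/104", N - (nA %/% 2) - (nA %% 2)))
  }
  N <- 5
  g <- genotype_table(rep(c("p1", "p2"), each = N), paste0("i", 1:(2 * N)),
                      data.frame(L1 = c(mk(0.7, N), mk(0.3, N))))
  hs <- (2 * N / (2 * N - 1)) * (1 - (0.7^2 + 0.3^2))
  ht <- (1 - 2 * 0.5^2) + hs / (2 * N * 2)
  d_expect <- ((ht - hs) / (1 - hs)) * 2
  expect_equal(jost_dest(g)$pairwise[1, 2], max(d_expect, 0),
               tolerance = 1e-12)
  # infinite-sample limit approx 0.2759 at large N
  N2 <- 5000
  g2 <- genotype_table(rep(c("p1", "p2"), each = N2),
                       paste0("i", 1:(2 * N2)),
                       data.frame(L1 = c(mk(0.7, N2), mk(0.3, N2))))
  expect_equal(jost_dest(g2)$pairwise[1, 2], 0.08 / 0.58 * 2,
               tolerance = 0.01)
  expect_error(jost_dest(genotype_table("p1", "i1",
                                        data.frame(L1 = "1/2"))),
               "two populations")
})

test_that("multi-locus D combines H components across loci", {
  g <- genotype_table(
    rep(c("p1", "p2"), each = 4), paste0("i", 1:8),
    data.frame(L1 = c(rep("100/100", 4), rep("104/104", 4)),
               L2 = rep("100/100", 8)))
  res <- jost_dest(g)
  # monomorphic locus contributes D = 0 per locus...
  expect_equal(res$per_locus$L2[1, 2], 0)
  expect_equal(res$per_locus$L1[1, 2], 1)
  # ...and dilutes the combined estimate through the H means
  expect_lt(res$pairwise[1, 2], 1)
  expect_gt(res$pairwise[1, 2], 0)
})

test_that("slope convergence tracks subset variability", {
  set.seed(5)
  pred <- dm_of_points(matrix(rnorm(27), 9, 3))
  # exact linear relation: every subset slope equals 2
  resp <- 2 * pred
  sc <- slope_convergence(resp, pred, max_removed = 3, n_draws = 20,
                          seed = 1)
  expect_identical(length(sc$slopes[["0"]]), 1L)
  lt <- lower.tri(pred)
  full_slope <- cov(pred[lt], resp[lt]) / var(pred[lt])
  expect_equal(sc$slopes[["0"]], full_slope)
  expect_true(all(abs(unlist(sc$slopes) - 2) < 1e-10))
  # with noise the slope spread widens as samples are removed
  noise <- matrix(rnorm(81), 9, 9); noise <- abs(noise + t(noise))
  diag(noise) <- 0
  resp2 <- 2 * pred + noise; dimnames(resp2) <- dimnames(pred)
  sc2 <- slope_convergence(resp2, pred, max_removed = 5, n_draws = 200,
                           seed = 2)
  expect_gte(sc2$summary$sd[6], sc2$summary$sd[2] - 0.05)
  expect_error(slope_convergence(resp2, pred, max_removed = 7), "at least 3")
})
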
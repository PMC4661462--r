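test_that("PERMANOVA pseudo-F reduces to one-way ANOVA F on univariate data", {
  set.seed(1)
  y <- rnorm(12)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- dm_of_points(y)
  f_aov <- anova(lm(y ~ g))[["F value"]][1]
  res <- permanova(d, g, n_perm = 99, seed = 1)
  expect_lt(abs(res$pseudo_F - f_aov), 1e-10)
  expect_identical(res$df_between, 2L)
  expect_identical(res$df_within, 9L)
  expect_lt(abs(res$ss_total - (res$ss_between + res$ss_within)), 1e-9)
  expect_gte(res$R2, 0); expect_lte(res$R2, 1)
})

test_that("PERMANOVA agrees with vegan::adonis2 and respects invariances", {
  skip_if_not_installed("vegan")
  set.seed(2)
  x <- matrix(rnorm(36), 12, 3)
  d <- dm_of_points(x)
  g <- rep(c("a", "b"), each = 6)
  res <- permanova(d, g, n_perm = 99, seed = 1)
  ad <- vegan::adonis2(as.dist(d) ~ g, permutations = 9)
  expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ad$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA is invariant to reordering and relabeling (n = 6)", {
  set.seed(3)
  d <- dm_of_points(rnorm(6))
  g <- c("a", "a", "a", "b", "b", "b")
  r1 <- permanova(d, setNames(g, rownames(d)), n_perm = 720, seed = 1)
  ix <- sample(6)
  r2 <- permanova(d[ix, ix], setNames(g, rownames(d))[ix],
                  n_perm = 720, seed = 9)
  r3 <- permanova(d, setNames(c("x", "x", "x", "y", "y", "y"),
                              rownames(d)), n_perm = 720, seed = 5)
  expect_true(r1$exhaustive)
  expect_equal(r1$pseudo_F, r2$pseudo_F)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$p, r3$p)
  expect_error(permanova(d, rep("a", 6)), "two groups")
})

test_that("ANOSIM matches its rank construction and vegan", {
  # complete separation: R = 1
  x <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- dm_of_points(x)
  g <- rep(c("a", "b"), each = 3)
  expect_equal(anosim_test(d, g, n_perm = 99, seed = 1)$R, 1)
  # all distances equal: R = 0 via mid-ranks
  de <- matrix(1, 6, 6); diag(de) <- 0
  dimnames(de) <- dimnames(d)
  expect_equal(anosim_test(de, g, n_perm = 99, seed = 1)$R, 0)
  skip_if_not_installed("vegan")
  set.seed(4)
  d2 <- dm_of_points(matrix(rnorm(30), 10, 3))
  g2 <- rep(c("a", "b"), each = 5)
  expect_equal(anosim_test(d2, g2, n_perm = 99, seed = 1)$R,
               unname(vegan::anosim(as.dist(d2), g2,
                                    permutations = 9)$statistic),
               tolerance = 1e-12)
})

test_that("ANOSIM R is centred on zero under exchangeable labels", {
  set.seed(5)
  rs <- replicate(100, {
    d <- dm_of_points(matrix(rnorm(27), 9, 3))
    g <- sample(rep(c("a", "b"), c(4, 5)))
    anosim_test(d, g, n_perm = 19, seed = 1)$R
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("dispersion test detects scale differences and rejects degenerate input", {
  set.seed(6)
  base <- matrix(rnorm(40), 20, 2)
  x <- rbind(base, 3 * matrix(rnorm(40), 20, 2))
  d <- dm_of_points(x)
  g <- rep(c("tight", "wide"), each = 20)
  res <- dispersion_test(d, g, n_perm = 199, seed = 1)
  expect_lte(res$p, 0.05)
  expect_identical(res$df1, 1L)
  expect_identical(res$df2, 38L)
  expect_error(dispersion_test(d, rep("a", 40)), "two groups")
  g1 <- c("a", rep("b", 39))
  expect_warning(dispersion_test(d, g1, n_perm = 19, seed = 1), "size 1")
})

test_that("core microbiome applies the ceiling prevalence threshold", {
  m <- matrix(0L, 9, 3, dimnames = list(paste0("s", 1:9),
                                        c("seven", "six", "all")))
  m[1:7, "seven"] <- 1L
  m[1:6, "six"] <- 1L
  m[, "all"] <- 1L
  tab <- otu_table(m)
  core <- core_microbiome(tab, min_fraction = 0.77)
  expect_setequal(core, c("all", "seven"))   # ceil(0.77 * 9) = 7
  expect_identical(core_microbiome(tab, min_fraction = 1), "all")
  expect_true("all" %in% core_microbiome(tab, min_fraction = 0.01))
  expect_error(core_microbiome(tab, min_fraction = 0), "min_fraction")
})

test_that("differential features combine Welch tests, BH and the effect filter", {
  set.seed(7)
  rel <- matrix(runif(40, 0.1, 0.2), 8, 5,
                dimnames = list(paste0("s", 1:8), paste0("f", 1:5)))
  g <- rep(c("egg", "water"), each = 4)
  # identical groups: nothing significant
  rel_id <- rel; rel_id[5:8, ] <- rel_id[1:4, ]
  res0 <- differential_features(rel_id, g)
  expect_true(all(!res0$significant))
  expect_true(all(res0$p == 1 | res0$t == 0 | res0$p > 0.05))
  # a strong shift passes; a small shift (< 5 points) is filtered out
  rel2 <- rel
  rel2[5:8, "f1"] <- rel2[5:8, "f1"] + 0.4           # large difference
  rel2[1:4, "f2"] <- 0.15 + rnorm(4, 0, 1e-6)        # tiny, precise diff
  rel2[5:8, "f2"] <- 0.18 + rnorm(4, 0, 1e-6)
  res <- differential_features(rel2, g)
  expect_true(res$significant[res$feature == "f1"])
  f2 <- res[res$feature == "f2", ]
  expect_lt(f2$p_adjusted, 0.05)
  expect_false(f2$significant)                       # mean-diff filter
  # features absent from one group are not compared
  rel3 <- rel2; rel3[1:4, "f3"] <- 0
  expect_false("f3" %in% differential_features(rel3, g)$feature)
  # Welch t and df match stats::t.test
  tt <- t.test(rel2[1:4, "f1"], rel2[5:8, "f1"])
  r1 <- res[res$feature == "f1", ]
  expect_equal(r1$t, unname(tt$statistic))
  expect_equal(r1$df, unname(tt$parameter))
  expect_error(differential_features(rel2[c(1, 5), ], g[c(1, 5)]),
               ">= 2 samples")
})
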
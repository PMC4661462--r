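test_that("chao1 matches its defining formula", {
  expect_identical(chao1(c(5, 7, 9)), 3)             # no singletons
  expect_identical(chao1(c(1, 1, 2, 5)), 4.5)        # 4 + 2*1/(2*2)
  expect_identical(chao1(1), 1)                      # single singleton
  expect_error(chao1(c(0, 0)), "all-zero")
  # classic variant
  expect_identical(chao1(c(1, 1, 2, 5), bias_corrected = FALSE), 6)
})

test_that("observed_species counts positive OTUs", {
  expect_identical(observed_species(c(0, 0, 3)), 1L)
  expect_identical(observed_species(1:5), 5L)
  expect_identical(observed_species(c(0, 0)), 0L)
})

test_that("faith_pd spans present tips and the root", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3);")
  expect_equal(faith_pd(c(A = 1, B = 1, C = 1), tr), 7)  # whole tree
  expect_equal(faith_pd(c(A = 1, B = 0, C = 0), tr), 2)  # A -> root
  expect_equal(faith_pd(c(A = 0, B = 0, C = 0), tr), 0)  # empty community
  expect_error(faith_pd(c(A = 1, X = 2), tr), "missing from the tree")
  # excluding the root drops the shared stem
  expect_equal(faith_pd(c(A = 1, B = 1, C = 0), tr, include_root = FALSE), 3)
  expect_equal(faith_pd(c(A = 1, B = 0, C = 0), tr, include_root = FALSE), 0)
})

test_that("faith_pd is monotone under taxon addition", {
  set.seed(42)
  for (i in 1:25) {
    tr <- random_tree_instance(sample(4:12, 1))
    present <- random_presence(tr$tip.label)
    absent <- setdiff(tr$tip.label, present)
    if (length(absent) == 0) next
    v1 <- setNames(as.integer(tr$tip.label %in% present), tr$tip.label)
    v2 <- v1; v2[sample(absent, 1)] <- 1L
    expect_gte(faith_pd(v2, tr), faith_pd(v1, tr))
  }
})

test_that("rarefaction subsamples without replacement", {
  x <- setNames(c(10L, 5L, 0L, 1L), paste0("o", 1:4))
  expect_identical(rarefy_counts(x, 16), x)             # depth = total
  one <- rarefy_counts(x, 1, seed = 1)
  expect_identical(sum(one), 1L)
  expect_identical(names(one), names(x))
  expect_error(rarefy_counts(x, 17), "exceeds")
  # E[observed species at depth d] matches the hypergeometric closed form
  counts <- c(12L, 7L, 3L, 2L, 1L, 1L)
  N <- sum(counts); d <- 10
  closed <- sum(1 - choose(N - counts, d) / choose(N, d))
  set.seed(99)
  mc <- replicate(1000, sum(rarefy_counts(counts, d) > 0))
  se <- sd(mc) / sqrt(1000)
  expect_lt(abs(mean(mc) - closed), 4 * se)
})

test_that("alpha_table honors depth policy and estimator inequalities", {
  set.seed(8)
  m <- matrix(rpois(40, 6), 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("o", 1:10)))
  tab <- otu_table(m)
  tr <- random_tree_instance(10)
  tr$tip.label <- paste0("o", 1:10)
  a <- alpha_table(tab, tr, n_reps = 5, seed = 2)
  expect_setequal(unique(a$metric),
                  c("chao1", "observed_species", "faith_pd"))
  for (s in rownames(m)) {
    ch <- a$mean[a$sample_id == s & a$metric == "chao1"]
    os <- a$mean[a$sample_id == s & a$metric == "observed_species"]
    expect_gte(ch, os)
  }
  # raw metrics when depth = own total and n_reps = 1
  a1 <- alpha_table(otu_table(m[1, , drop = FALSE]), tree = NULL,
                    depth = sum(m[1, ]), n_reps = 1)
  expect_identical(a1$mean[a1$metric == "observed_species"],
                   as.numeric(sum(m[1, ] > 0)))
  # deeper rarefaction never loses species on average
  shallow <- alpha_table(tab, NULL, depth = 5, n_reps = 20, seed = 3)
  deep <- alpha_table(tab, NULL, depth = min(rowSums(m)), n_reps = 20,
                      seed = 4)
  os_s <- shallow[shallow$metric == "observed_species", ]
  os_d <- deep[deep$metric == "observed_species", ]
  expect_true(all(os_d$mean >= os_s$mean -
                    2 * (os_s$sd + os_d$sd) / sqrt(20)))
})

test_that("rarefaction curves are monotone within error", {
  set.seed(10)
  m <- matrix(rpois(20, 8), 2, 10,
              dimnames = list(c("s1", "s2"), paste0("o", 1:10)))
  rc <- rarefaction_curves(otu_table(m), depths = c(5, 20, 40),
                           n_reps = 30, seed = 5)
  for (s in c("s1", "s2")) {
    os <- rc[rc$sample_id == s & rc$metric == "observed_species", ]
    os <- os[order(os$depth), ]
    expect_true(all(diff(os$mean) > -2 * max(os$sd) / sqrt(30)))
  }
})

test_that("unweighted UniFrac matches hand-computed cases", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- matrix(c(1L, 1L, 0L, 0L,
                1L, 0L, 1L, 0L,
                1L, 1L, 0L, 0L), 3, 4, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("A", "B", "C", "D")))
  u <- unifrac(otu_table(m), tr)
  expect_equal(u["s1", "s2"], 0.6)        # unique 3 / union 5
  expect_equal(u["s1", "s3"], 0)          # identical presence profiles
  # disjoint subtrees joined only at the root: distance 1
  m2 <- matrix(c(1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L), 2, 4, byrow = TRUE,
               dimnames = list(c("x", "y"), c("A", "B", "C", "D")))
  expect_equal(unifrac(otu_table(m2), tr)["x", "y"], 1)
  # zero-taxon community is undefined
  m3 <- rbind(m, s4 = c(0L, 0L, 0L, 0L))
  expect_error(unifrac(otu_table(m3), tr), "zero taxa")
  # optional rarefaction pre-step is deterministic given the seed
  m4 <- matrix(c(5L, 9L, 2L, 0L, 4L, 0L, 3L, 8L), 2, 4,
               dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
  u1 <- unifrac(otu_table(m4), tr, rarefy_depth = 6, seed = 3)
  u2 <- unifrac(otu_table(m4), tr, rarefy_depth = 6, seed = 3)
  expect_identical(u1, u2)
})

test_that("unweighted UniFrac is a pseudometric on random instances", {
  set.seed(77)
  for (i in 1:20) {
    tr <- random_tree_instance(sample(5:12, 1))
    k <- sample(3:5, 1)
    m <- matrix(0L, k, length(tr$tip.label),
                dimnames = list(paste0("s", 1:k), tr$tip.label))
    for (r in 1:k) m[r, random_presence(tr$tip.label)] <- 1L
    u <- unifrac(otu_table(m), tr)
    expect_equal(u, t(u))
    expect_true(all(diag(u) == 0))
    for (a in 1:k) for (b in 1:k) for (cc in 1:k)
      expect_lte(u[a, b], u[a, cc] + u[cc, b] + 1e-12)
  }
})

test_that("weighted UniFrac responds to abundance shifts", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- matrix(c(99L, 1L, 0L, 0L, 1L, 99L, 0L, 0L), 2, 4, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
  uw <- unifrac(otu_table(m), tr, weighted = FALSE)
  w <- unifrac(otu_table(m), tr, weighted = TRUE)
  expect_equal(uw["s1", "s2"], 0)   # same presence profile
  expect_gt(w["s1", "s2"], 0)       # but very different abundances
})

test_that("principal coordinates reproduce Euclidean configurations", {
  set.seed(12)
  x <- matrix(rnorm(24), 6, 4)
  d <- dm_of_points(x)
  pc <- principal_coordinates(d)
  expect_lt(max(abs(as.matrix(dist(pc$coordinates)) - d)), 1e-8)
  # two points: one axis at +/- d/2
  d2 <- matrix(c(0, 0.6, 0.6, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  pc2 <- principal_coordinates(d2)
  expect_identical(ncol(pc2$coordinates), 1L)
  expect_equal(unname(sort(pc2$coordinates[, 1])), c(-0.3, 0.3))
})

test_that("non-Euclidean distances yield negative eigenvalues, Cailliez cures them", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 1.99  # violates the Euclidean embedding
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  pc <- principal_coordinates(d)
  expect_true(any(pc$eigenvalues < -1e-8))
  expect_true(ncol(pc$coordinates) >= 1)
  # sign pattern agrees with a direct eigendecomposition
  G <- eggbiome:::double_centre(-0.5 * d^2)
  expect_equal(sort(pc$eigenvalues), sort(eigen(G)$values))
  pcc <- principal_coordinates(d, correction = "cailliez")
  expect_gt(pcc$correction_constant, 0)
  expect_gt(min(pcc$eigenvalues), -1e-6)
})
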
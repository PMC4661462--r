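test_that("OTU table TSV round-trips identically and follows the dialect", {
  m <- matrix(c(3L, 0L, 0L, 5L), 2, 2,
              dimnames = list(c("s1", "s2"), c("otu1", "otu2")))
  tab <- otu_table(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, f)
  back <- read_otu_table(f)
  expect_identical(unclass(back), unclass(tab))
  expect_identical(rownames(back), c("s1", "s2"))
  # dialect: file is OTU x samples with a "#OTU_ID" header
  lines <- readLines(f)
  expect_identical(lines[1], "#OTU_ID\ts1\ts2")
  expect_identical(lines[2], "otu1\t3\t0")
})

test_that("a file written OTU x samples is transposed on read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "#OTU_ID\tsA\tsB",
               "otu1\t3\t0", "otu2\t0\t5"), f)
  tab <- read_otu_table(f)
  expect_identical(dim(tab), c(2L, 2L))
  expect_identical(tab["sA", "otu1"], 3L)
  expect_identical(tab["sB", "otu2"], 5L)
})

test_that("invalid OTU tables are rejected with informative errors", {
  m <- matrix(c(3, -1, 0, 5), 2, 2,
              dimnames = list(c("s1", "s2"), c("o1", "o2")))
  expect_error(otu_table(m), "s2.*o1")
  m2 <- matrix(1L, 2, 2, dimnames = list(c("s1", "s1"), c("o1", "o2")))
  expect_error(otu_table(m2), "duplicate sample")
  m3 <- matrix(0.5, 1, 1, dimnames = list("s1", "o1"))
  expect_error(otu_table(m3), "non-integer")
})

test_that("Newick round-trip preserves tips and total branch length", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:2):1,C:3);", f)
  tr <- read_phylogeny(f)
  expect_identical(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(sum(tr$edge.length), 7)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_phylogeny(tr, f2)
  tr2 <- read_phylogeny(f2)
  expect_identical(sort(tr2$tip.label), sort(tr$tip.label))
  expect_lt(abs(sum(tr2$edge.length) - sum(tr$edge.length)), 1e-9)
})

test_that("trees without branch lengths or with duplicate tips error", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B),C);", f)
  expect_error(read_phylogeny(f), "branch length")
  f2 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,A:2):1,C:3);", f2)
  expect_error(read_phylogeny(f2), "duplicate tip")
})

test_that("distance matrix IO symmetrizes tiny asymmetries and rejects bad input", {
  d <- matrix(c(0, 0.5, 0.2, 0.5 + 1e-9, 0, 0.3, 0.2, 0.3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d, f)
  back <- read_distance_matrix(f)
  expect_identical(rownames(back), c("a", "b", "c"))
  expect_equal(back["a", "b"], 0.5 + 5e-10, tolerance = 1e-12)
  expect_identical(back, t(back))
  # diagonal must be zero
  d2 <- d; d2[2, 2] <- 0.1
  expect_error(write_distance_matrix(d2, f), "diagonal")
  # large asymmetry is an error, not silently averaged
  d3 <- d; d3[1, 2] <- 0.6
  expect_error(write_distance_matrix(d3, f), "asymmetric")
})

test_that("metadata validation enforces vocabulary, dates and control count", {
  md <- data.frame(sample_id = c("e1", "nc"),
                   location_id = c("l1", "l1"),
                   sample_type = c("egg", "negative_control"),
                   river_group = c("main_river", "main_river"),
                   latitude = 46.5, longitude = 7.4, elevation_m = 500,
                   spawn_date = "2010-01-01", sample_date = "2010-02-15")
  ok <- validate_metadata(md)
  expect_s3_class(ok, "study_metadata")
  bad <- md; bad$sample_type[1] <- "mud"
  expect_error(validate_metadata(bad), "unknown sample_type")
  bad2 <- md; bad2$sample_date <- "2009-12-01"
  expect_error(validate_metadata(bad2), "earlier than spawn_date")
  bad3 <- md; bad3$sample_type <- "negative_control"
  expect_error(validate_metadata(bad3), "more than one negative_control")
})

test_that("genotype IO parses diploid cells and rejects malformed ones", {
  gt <- genotype_table(c("p1", "p1", "p2"), c("i1", "i2", "i3"),
                       data.frame(L1 = c("120/124", "./.", "120/120")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gt, f)
  back <- read_genotypes(f)
  expect_identical(back$L1, c("120/124", NA, "120/120"))
  af <- eggbiome:::allele_frequencies(back)
  # missing genotype excluded from frequency sums
  expect_identical(af$L1$p1$n, 1L)
  expect_equal(as.numeric(af$L1$p1$freq), c(0.5, 0.5))
  expect_error(
    genotype_table("p1", "i1", data.frame(L1 = "120/124/128")),
    "exactly two alleles")
  expect_error(
    genotype_table(c("p1", "p2"), c("i1", "i1"),
                   data.frame(L1 = c("1/2", "1/2"))),
    "two populations")
})

test_that("temperature series validation checks ordering and plausibility", {
  ts <- data.frame(location_id = "l1",
                   timestamp = c("2010-01-01T00:00:00",
                                 "2010-01-01T00:10:00"),
                   temperature_c = c(4, 4.1))
  expect_s3_class(validate_temperature_series(ts), "temperature_series")
  bad <- ts[c(2, 1), ]
  expect_error(validate_temperature_series(bad), "strictly increasing")
  bad2 <- ts; bad2$temperature_c[1] <- 99
  expect_error(validate_temperature_series(bad2), "plausibility")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_temperature_series(validate_temperature_series(ts), f)
  back <- read_temperature_series(f)
  expect_equal(back$temperature_c, ts$temperature_c)
})
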
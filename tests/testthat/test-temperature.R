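test_that("Kendall tau matches pair enumeration and cor.test", {
  expect_equal(kendall_tau(1:6, 1:6)$tau, 1)
  expect_equal(kendall_tau(1:6, 6:1)$tau, -1)
  k <- kendall_tau(c(1, 2, 3), c(1, 3, 2))
  expect_identical(k$concordant, 2L)
  expect_identical(k$discordant, 1L)
  expect_equal(k$tau, 1 / 3)
  # tie handling against cor.test's tau and z
  set.seed(1)
  for (i in 1:10) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- sample(1:5, 12, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
    kk <- kendall_tau(x, y, tail = "two.sided")
    expect_equal(kk$tau, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(kk$z, unname(ct$statistic), tolerance = 1e-12)
  }
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
})

test_that("exact Kendall p agrees with full enumeration", {
  set.seed(2)
  x <- rnorm(6); y <- rnorm(6)
  ke <- kendall_tau(x, y, tail = "greater", exact = TRUE)
  # oracle: enumerate all orderings of y
  perms <- oracle_perms(1:6)
  taus <- apply(perms, 1, function(ix) oracle_kendall_tau(x, y[ix]))
  tau_obs <- oracle_kendall_tau(x, y)
  expect_equal(ke$p, mean(taus >= tau_obs - 1e-12), tolerance = 1e-12)
  expect_error(kendall_tau(rnorm(9), rnorm(9), exact = TRUE), "n <= 8")
})

test_that("period means partition the incubation into calendar-day spans", {
  mk_series <- function(temps_fun, days = 10) {
    tt <- seq(as.POSIXct("2010-01-01 00:00:00", tz = "UTC"),
              by = 600, length.out = days * 144)
    frac <- as.numeric(tt - tt[1], units = "days") / days
    validate_temperature_series(data.frame(
      location_id = "l1", timestamp = tt,
      temperature_c = temps_fun(frac)))
  }
  # constant series: every period mean is the constant
  pm <- period_means(mk_series(function(f) rep(4, length(f))),
                     "2010-01-01", "2010-01-11", k = 5)
  expect_equal(pm$period_means, rep(4, 5))
  expect_equal(pm$overall_mean, 4)
  # linear ramp 0 -> 10 degC: period means 1, 3, 5, 7, 9
  pm2 <- period_means(mk_series(function(f) 10 * f),
                      "2010-01-01", "2010-01-11", k = 5)
  expect_equal(pm2$period_means, c(1, 3, 5, 7, 9), tolerance = 0.05)
  # k = 1 degenerates to the overall mean
  pm1 <- period_means(mk_series(function(f) 10 * f),
                      "2010-01-01", "2010-01-11", k = 1)
  expect_equal(pm1$period_means, pm1$overall_mean)
  # overall mean is the duration-weighted mean of period means
  pm3 <- period_means(mk_series(function(f) 10 * f, days = 11),
                      "2010-01-01", "2010-01-12", k = 5)
  expect_equal(pm3$overall_mean,
               sum(pm3$period_means * pm3$period_days) /
                 sum(pm3$period_days), tolerance = 1e-9)
  expect_equal(pm3$period_days, c(2, 2, 2, 2, 3))  # remainder to the last
  # a coverage gap larger than one day is an error
  s <- mk_series(function(f) rep(4, length(f)))
  gap <- s[!(s$timestamp >= as.POSIXct("2010-01-03", tz = "UTC") &
               s$timestamp < as.POSIXct("2010-01-05", tz = "UTC")), ]
  expect_error(period_means(validate_temperature_series(gap),
                            "2010-01-01", "2010-01-11", k = 5),
               "coverage gap")
})

test_that("period means are invariant to logger cadence for piecewise-constant series", {
  mk <- function(step_s) {
    tt <- seq(as.POSIXct("2010-01-01 00:00:00", tz = "UTC"),
              by = step_s, length.out = 10 * 86400 / step_s)
    day <- floor(as.numeric(tt - tt[1], units = "days"))
    validate_temperature_series(data.frame(
      location_id = "l1", timestamp = tt,
      temperature_c = c(2, 2, 3, 3, 4, 4, 5, 5, 6, 6)[day + 1]))
  }
  pm_a <- period_means(mk(600), "2010-01-01", "2010-01-11", k = 5)
  pm_b <- period_means(mk(3600), "2010-01-01", "2010-01-11", k = 5)
  expect_equal(pm_a$period_means, pm_b$period_means, tolerance = 1e-9)
  expect_equal(pm_a$period_means, c(2, 3, 4, 5, 6))
})

test_that("forward stepwise selects signal and stops on noise", {
  set.seed(3)
  X <- matrix(rnorm(200), 40, 5,
              dimnames = list(NULL, paste0("period_", 1:5)))
  # noiseless: the driving covariate enters first, R2 = 1, then stop
  y <- 2 + 3 * X[, 1]
  sw <- forward_stepwise(y, X)
  expect_identical(sw$selected, "period_1")
  expect_equal(sw$steps$cumulative_R2[1], 1)
  # cumulative R2 reaches the full-model R2 when all candidates enter
  y2 <- X %*% c(1, -1, 2, 0.5, -0.7) + rnorm(40, 0, 0.01)
  sw2 <- forward_stepwise(y2, X)
  full_r2 <- summary(lm(y2 ~ X))$r.squared
  expect_identical(length(sw2$selected), 5L)
  expect_equal(sw2$steps$cumulative_R2[5], full_r2, tolerance = 1e-9)
  expect_true(all(diff(sw2$steps$cumulative_R2) >= 0))
  # model F carries (q, n - q - 1) degrees of freedom
  expect_identical(sw2$steps$df1, 1:5)
  expect_identical(sw2$steps$df2, 40L - 1:5 - 1L)
  # perfectly collinear candidates are dropped with a warning once their
  # duplicate is in the model
  yc <- X[, 1] + X[, 2] + rnorm(40, 0, 0.1)
  Xc <- cbind(X[, 1:2], dup = X[, 1])
  expect_warning(swc <- forward_stepwise(yc, Xc), "collinear")
  expect_false("dup" %in% swc$selected)
})

test_that("temperature association bundles Kendall and partial Mantel", {
  set.seed(4)
  st <- simulate_study(simulation_config(seed = 31))
  dec <- remove_control_otus(st$table, st$metadata)
  eggs <- st$ground_truth$egg_sample_ids
  alpha <- alpha_table(otu_table(unclass(dec$table)[eggs, ]), NULL,
                       n_reps = 2, seed = 1)
  loc_of <- setNames(st$metadata$location_id, st$metadata$sample_id)
  conn <- names(st$ground_truth$mean_temperature)[-1]
  u <- unifrac(otu_table(unclass(dec$table)[eggs, ]), st$tree)
  u_loc <- u[paste0("egg_", conn), paste0("egg_", conn)]
  dimnames(u_loc) <- list(conn, conn)
  geo <- st$geo_distance[conn, conn]
  res <- temperature_association(alpha, st$ground_truth$mean_temperature,
                                 u_loc, geo, location_of = loc_of,
                                 n_perm = 99, seed = 1)
  expect_setequal(names(res$kendall), c("chao1", "observed_species"))
  for (k in res$kendall) expect_s3_class(k, "kendall_result")
  expect_s3_class(res$partial_mantel, "mantel_result")
  # a constant temperature vector gives a degenerate |dT| matrix
  const_t <- setNames(rep(4, length(conn) + 1),
                      c(names(st$ground_truth$mean_temperature)))
  expect_error(temperature_association(alpha, const_t, u_loc, geo,
                                       location_of = loc_of, n_perm = 9),
               "constant")
})
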
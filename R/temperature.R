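#' Kendall rank correlation with tie-corrected normal approximation
#'
#' Tau-b with tie corrections in both margins. The z statistic uses the
#' standard tie-adjusted null variance of `S = C - D` (without ties it
#' reduces to `z = 3 S / sqrt(n(n-1)(2n+5)/2)`); the p-value is one-sided
#' from the normal tail by default. For `n <= 8` an exact permutation
#' p-value is available.
#'
#' @param x,y Numeric vectors of equal length (`n >= 3`), neither constant.
#' @param tail `"greater"` (default), `"less"`, or `"two.sided"`.
#' @param exact Use exact enumeration of all `n!` orderings (only for
#'   `n <= 8`).
#' @return List of class `kendall_result`: `tau`, `z`, `p`, `n`,
#'   `concordant`, `discordant`, `ties_x`, `ties_y`, `tail`, `exact`.
#' @export
kendall_tau <- function(x, y, tail = c("greater", "less", "two.sided"),
                        exact = FALSE) {
  tail <- match.arg(tail)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector: tau undefined", call. = FALSE)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  prod_ut <- (sx * sy)[upper.tri(sx)]
  C <- sum(prod_ut > 0)
  D <- sum(prod_ut < 0)
  S <- C - D
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  t1 <- sum(tx * (tx - 1) / 2)
  u1 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - t1) * (n0 - u1))
  # tie-adjusted null variance of S (as in the classical normal approx)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  v <- (v0 - vt - vu) / 18 + v1 + v2
  z <- S / sqrt(v)
  if (exact) {
    if (n > 8) stop("exact enumeration limited to n <= 8", call. = FALSE)
    perms <- all_permutations(n)
    s_null <- apply(perms, 1L, function(ix) {
      pr <- (sx * sign(outer(y[ix], y[ix], "-")))[upper.tri(sx)]
      sum(pr > 0) - sum(pr < 0)
    })
    p <- switch(tail,
      greater = mean(s_null >= S),
      less = mean(s_null <= S),
      two.sided = mean(abs(s_null) >= abs(S)))
  } else {
    p <- switch(tail,
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z),
      two.sided = 2 * pnorm(abs(z), lower.tail = FALSE))
  }
  structure(list(tau = tau, z = z, p = p, n = n, concordant = C,
                 discordant = D, ties_x = t1, ties_y = u1, tail = tail,
                 exact = exact),
            class = "kendall_result")
}

#' @export
print.kendall_result <- function(x, ...) {
  cat(sprintf("Kendall: tau = %.3g, z = %.3g, p = %.3g (%s, n = %d)\n",
              x$tau, x$z, x$p, x$tail, x$n))
  invisible(x)
}

#' Mean temperatures over equal incubation periods
#'
#' Splits the incubation interval `[spawn_date, sample_date)` into `k`
#' consecutive periods of equal length in calendar days (remainder days go
#' to the last period) and averages the logger readings whose timestamps
#' fall in each half-open period `[start, end)`. The overall mean is the
#' duration-weighted mean of the period means.
#'
#' @param series A `temperature_series` (single location, or pass
#'   `location_id`).
#' @param spawn_date,sample_date `Date`s bounding the incubation.
#' @param k Number of periods (default 5).
#' @param location_id Optional location filter.
#' @param max_gap_days Largest tolerated gap between consecutive readings
#'   (default 1 day).
#' @return List of class `period_means`: `location_id`, `period_means`
#'   (length `k`), `period_days`, `overall_mean`, `overall_sd`, `k`.
#' @export
period_means <- function(series, spawn_date, sample_date, k = 5,
                         location_id = NULL, max_gap_days = 1) {
  stopifnot(k >= 1)
  ts <- as.data.frame(series)
  if (!is.null(location_id)) ts <- ts[ts$location_id == location_id, ]
  if (nrow(ts) == 0) stop("no readings for this location", call. = FALSE)
  spawn_date <- as.Date(spawn_date); sample_date <- as.Date(sample_date)
  total_days <- as.integer(sample_date - spawn_date)
  if (total_days < k)
    stop("incubation shorter than the number of periods", call. = FALSE)
  t0 <- as.POSIXct(paste(spawn_date, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(sample_date, "00:00:00"), tz = "UTC")
  tt <- as.POSIXct(ts$timestamp, tz = "UTC")
  in_window <- tt >= t0 & tt < t1
  if (!any(in_window))
    stop("series does not cover the incubation interval", call. = FALSE)
  tw <- tt[in_window]; xw <- ts$temperature_c[in_window]
  gaps <- diff(as.numeric(tw)) / 86400
  cover_gaps <- c(as.numeric(tw[1] - t0, units = "days"), gaps,
                  as.numeric(t1 - tw[length(tw)], units = "days"))
  if (max(cover_gaps) > max_gap_days) {
    gi <- which.max(cover_gaps)
    stop(sprintf("coverage gap of %.2f days within the incubation interval",
                 max(cover_gaps)), call. = FALSE)
  }
  base_len <- total_days %/% k
  starts <- t0 + (seq_len(k) - 1) * base_len * 86400
  ends <- c(starts[-1], t1)
  pm <- numeric(k); pd <- numeric(k)
  for (i in seq_len(k)) {
    sel <- tw >= starts[i] & tw < ends[i]
    pm[i] <- mean(xw[sel])
    pd[i] <- as.numeric(ends[i] - starts[i], units = "days")
  }
  structure(list(location_id = location_id %||%
                   unique(ts$location_id)[1],
                 period_means = pm, period_days = pd,
                 overall_mean = sum(pm * pd) / sum(pd),
                 overall_sd = sd(xw), k = k),
            class = "period_means")
}

#' Forward stepwise regression with partial-F entry
#'
#' Starts from the empty model; at each step the candidate with the largest
#' partial F enters if its p-value is below `entry_p` (default 0.05).
#' Reports, per step, the entered covariate, its entry partial F and
#' p-value, the cumulative model F with `(q, n - q - 1)` degrees of
#' freedom, and the cumulative R-squared. Perfectly collinear candidates
#' are dropped with a warning.
#'
#' @param y Response vector.
#' @param X Numeric matrix or data frame of candidate covariates.
#' @param entry_p Entry threshold on the partial-F p-value (default 0.05).
#' @return List of class `stepwise_result`: `selected` (ordered names),
#'   `steps` (data frame: `covariate`, `partial_F`, `partial_p`,
#'   `model_F`, `df1`, `df2`, `model_p`, `cumulative_R2`),
#'   `coefficients` (final model), `entry_p`.
#' @export
forward_stepwise <- function(y, X, entry_p = 0.05) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  stopifnot(nrow(X) == n)
  selected <- character(0)
  candidates <- colnames(X)
  tss <- sum((y - mean(y))^2)
  rss_cur <- tss
  steps <- list()
  repeat {
    q_next <- length(selected) + 1L
    if (n <= q_next + 1L) break  # no residual df left for the entry test
    best <- NULL
    for (cand in candidates) {
      Xi <- cbind(1, X[, c(selected, cand), drop = FALSE])
      if (qr(Xi)$rank < ncol(Xi)) {
        warning("dropping perfectly collinear candidate: ", cand)
        candidates <- setdiff(candidates, cand)
        next
      }
      fit <- lm.fit(Xi, y)
      rss_new <- sum(fit$residuals^2)
      df2 <- n - q_next - 1L
      f_part <- (rss_cur - rss_new) / (rss_new / df2)
      if (is.null(best) || f_part > best$f_part)
        best <- list(cand = cand, f_part = f_part, rss = rss_new,
                     df2 = df2, coefs = fit$coefficients)
    }
    if (is.null(best)) break
    p_part <- pf(best$f_part, 1, best$df2, lower.tail = FALSE)
    if (p_part >= entry_p) break
    selected <- c(selected, best$cand)
    candidates <- setdiff(candidates, best$cand)
    rss_cur <- best$rss
    q <- length(selected)
    r2 <- 1 - rss_cur / tss
    model_f <- if (rss_cur > 0)
      ((tss - rss_cur) / q) / (rss_cur / (n - q - 1)) else Inf
    steps[[q]] <- data.frame(
      covariate = best$cand, partial_F = best$f_part, partial_p = p_part,
      model_F = model_f, df1 = q, df2 = n - q - 1L,
      model_p = pf(model_f, q, n - q - 1L, lower.tail = FALSE),
      cumulative_R2 = r2, stringsAsFactors = FALSE)
    if (r2 >= 1 - 1e-12 || length(candidates) == 0) break
  }
  coefs <- if (length(selected) > 0) {
    fit <- lm.fit(cbind(`(Intercept)` = 1,
                        X[, selected, drop = FALSE]), y)
    fit$coefficients
  } else c(`(Intercept)` = mean(y))
  structure(list(selected = selected,
                 steps = if (length(steps) > 0) do.call(rbind, steps)
                         else data.frame(),
                 coefficients = coefs, entry_p = entry_p),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  if (length(x$selected) == 0) {
    cat("Forward stepwise: empty model (no covariate met entry p <",
        x$entry_p, ")\n")
  } else {
    k <- nrow(x$steps)
    cat(sprintf(
      "Forward stepwise: selected %s; final F(%d,%d) = %.4g, p = %.4g, R2 = %.3f\n",
      paste(x$selected, collapse = ", "), x$steps$df1[k], x$steps$df2[k],
      x$steps$model_F[k], x$steps$model_p[k], x$steps$cumulative_R2[k]))
  }
  invisible(x)
}

#' Temperature-diversity association report
#'
#' Bundles the temperature analyses: Kendall rank correlation (one-sided,
#' increasing) of each alpha diversity metric against overall mean
#' incubation temperature, and a partial Mantel test of community distances
#' against the pairwise temperature-difference matrix `|T_i - T_j|` while
#' controlling for geographic distance.
#'
#' @param alpha Data frame from [alpha_table()] with one row per
#'   location-metric (sample ids must be location-identifiable via
#'   `location_of`).
#' @param mean_temperature Named vector of overall mean incubation
#'   temperature per location.
#' @param unifrac_d Community distance matrix (ids matching locations in
#'   `geo_d`).
#' @param geo_d Geographic distance matrix (control), or `NULL` to skip the
#'   partial Mantel step.
#' @param location_of Named vector mapping sample ids to location ids
#'   (default: identity).
#' @param n_perm Permutations for the partial Mantel test (default 999).
#' @param seed Integer seed.
#' @return List of class `temperature_association`: `kendall` (list per
#'   metric), `partial_mantel` (or `NULL`), `temperature_difference`
#'   (matrix used).
#' @export
temperature_association <- function(alpha, mean_temperature, unifrac_d,
                                    geo_d = NULL, location_of = NULL,
                                    n_perm = 999, seed = NULL) {
  alpha$location_id <- if (is.null(location_of)) alpha$sample_id
                       else unname(location_of[alpha$sample_id])
  kend <- list()
  for (met in unique(alpha$metric)) {
    sub <- alpha[alpha$metric == met, ]
    tt <- mean_temperature[sub$location_id]
    kend[[met]] <- kendall_tau(tt, sub$mean, tail = "greater")
  }
  pm <- NULL; tdiff <- NULL
  if (!is.null(geo_d)) {
    geo_d <- as_distance_matrix(geo_d, tol = 1e-8)
    ids <- rownames(geo_d)
    tv <- mean_temperature[ids]
    tdiff <- abs(outer(tv, tv, "-"))
    dimnames(tdiff) <- dimnames(geo_d)
    u <- check_same_ids(geo_d, as_distance_matrix(unifrac_d, tol = 1e-8))
    pm <- partial_mantel_test(u, tdiff, geo_d, n_perm = n_perm,
                              tail = "greater", seed = seed)
  }
  structure(list(kendall = kend, partial_mantel = pm,
                 temperature_difference = tdiff),
            class = "temperature_association")
}
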
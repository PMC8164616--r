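test_that("natural spline basis is natural, spans linear functions, rejects degeneracy", {
  set.seed(2)
  x <- sort(runif(200, -3, 3))
  b <- natural_spline_basis(x, 3)
  expect_equal(dim(b), c(200L, 3L))

  # least-squares fit of y = x on the basis reproduces y (plus intercept)
  y <- x
  fit <- stats::lm.fit(cbind(1, b), y)
  expect_lt(max(abs(fit$residuals)), 1e-10)

  # linear extension beyond the boundary knots: second differences of a
  # fine extrapolation grid vanish
  xx <- seq(max(x) + 0.5, max(x) + 2, length.out = 20)
  bb <- splines::ns(xx, knots = attr(b, "knots"),
                    Boundary.knots = attr(b, "boundary_knots"))
  for (j in 1:3) expect_lt(max(abs(diff(diff(bb[, j])))), 1e-8)

  # df = 1 gives a single column monotone in x
  b1 <- natural_spline_basis(x, 1)
  expect_equal(ncol(b1), 1L)
  expect_true(all(diff(b1[, 1]) >= 0) || all(diff(b1[, 1]) <= 0))

  expect_error(natural_spline_basis(rep(1:2, 10), 3), "distinct")
  expect_error(natural_spline_basis(x, 0), "positive integer")
})

test_that("dataset assembly lags everything equally and applies complete-case rules", {
  fx <- tiny_series(1, 120)
  cnt <- simulate_counts(fx$config, fx$pollutants$NO2, fx$weather)

  d14 <- build_cc_dataset(cnt, fx$pollutants$NO2, fx$weather, 14, 3)
  # 120 fully observed days lose exactly the 14 leading lag days
  expect_equal(nrow(d14) + attr(d14, "n_dropped_stratum_rows"), 120 - 14)

  # one injected missing exposure day drops exactly one more row
  holey <- fx$pollutants$NO2
  holey$value[60] <- NA
  d0 <- build_cc_dataset(cnt, fx$pollutants$NO2, fx$weather, 0, 3)
  d0h <- build_cc_dataset(cnt, holey, fx$weather, 0, 3)
  expect_equal(attr(d0h, "n_dropped_missing"),
               attr(d0, "n_dropped_missing") + 1L)

  # the lagged exposure equals the original series shifted by the lag
  idx <- match(d14$date, fx$pollutants$NO2$date)
  expect_equal(d14$exposure, fx$pollutants$NO2$value[idx - 14])

  # a stratum whose counts are all zero is absent from the dataset
  cnt0 <- cnt
  mon_apr <- format(cnt0$date, "%u") == "1" & format(cnt0$date, "%m") == "04"
  cnt0$count[mon_apr] <- 0L
  dz <- build_cc_dataset(cnt0, fx$pollutants$NO2, fx$weather, 0, 3)
  expect_false(any(format(dz$date, "%u") == "1" &
                   format(dz$date, "%m") == "04"))
})

test_that("conditional fit equals the stratum-dummy Poisson oracle", {
  # several seeded 200-day fixtures, with and without weather splines
  for (seed in 1:3) {
    cfg <- quick_sim_config(seed, beta = 0.02, lag = 0, n_days = 200,
                            temp_effect = c(0.002, 1e-4))
    p <- simulate_pollutants(cfg); w <- simulate_weather(cfg)
    cnt <- simulate_counts(cfg, p$NO2, w)
    for (df in c(0, 3)) {
      ds <- build_cc_dataset(cnt, p$NO2, w, lag = 0, spline_df = df)
      fit <- fit_conditional_poisson(ds)
      orc <- glm_dummy_oracle(ds)
      expect_true(fit$converged)
      expect_lt(abs(fit$beta - orc$beta) / abs(orc$beta), 1e-6)
      expect_lt(abs(fit$se - orc$se) / orc$se, 1e-6)
    }
  }
})

test_that("conditioning removes stratum-constant shifts in the exposure", {
  fx <- tiny_series(7, 150)
  cnt <- simulate_counts(fx$config, fx$pollutants$NO2, fx$weather)
  ds <- build_cc_dataset(cnt, fx$pollutants$NO2, fx$weather, 0, 0)
  fit <- fit_conditional_poisson(ds)

  shifted <- ds
  offsets <- stats::setNames(runif(length(unique(ds$stratum)), -50, 50),
                             unique(ds$stratum))
  shifted$exposure <- ds$exposure + offsets[ds$stratum]
  fit2 <- fit_conditional_poisson(shifted)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-7)
  expect_equal(fit2$se, fit$se, tolerance = 1e-7)
  expect_equal(fit2$log_likelihood, fit$log_likelihood, tolerance = 1e-6)
})

test_that("constant exposure within every stratum is flagged as non-identified", {
  fx <- tiny_series(3, 120)
  cnt <- simulate_counts(fx$config, fx$pollutants$NO2, fx$weather)
  ds <- build_cc_dataset(cnt, fx$pollutants$NO2, fx$weather, 0, 0)
  ts <- build_time_strata(ds$date)
  month_mean <- stats::ave(ds$exposure, ts$key)
  ds$exposure <- month_mean # constant within each stratum
  expect_error(fit_conditional_poisson(ds), "not identified")
})

test_that("Wald p-values match the normal tail probabilities", {
  expect_equal(wald_p(0, 1), 1)
  # oracle: standard normal quantiles
  expect_equal(wald_p(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_equal(wald_p(3.290527, 1), 0.001, tolerance = 1e-6)
  expect_equal(wald_p(-1.959964, 1), wald_p(1.959964, 1))
  expect_equal(wald_p(0.5 * 1.959964, 0.5), 0.05, tolerance = 1e-6)
  expect_error(wald_p(1, 0), "se")
  expect_error(wald_p(1, -2), "se")
})

test_that("relative risks exponentiate the slope over the increment", {
  fit <- list(beta = 0, se = 0.01, converged = TRUE)
  rr <- relative_risk(fit, 10)
  expect_equal(rr$rr, 1)
  expect_lt(rr$lower, 1); expect_gt(rr$upper, 1)

  fit$beta <- 0.001
  rr <- relative_risk(fit, 10)
  expect_equal(rr$rr, exp(0.01))
  expect_equal(rr$lower, exp((0.001 - stats::qnorm(0.975) * 0.01) * 10))
  expect_true(rr$lower <= rr$rr && rr$rr <= rr$upper)

  expect_error(relative_risk(list(beta = 1, se = 1, converged = FALSE), 1),
               "converged")
  expect_error(relative_risk(fit, 0), "increment")

  s <- exposure_series(as.Date("2005-01-01") + 0:99, 0:99, "NO2")
  expect_equal(iqr_increment(s), stats::IQR(0:99))
})
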
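test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(n_days = 30), ">= 60")
  expect_error(sim_config(baseline_rate = 0), "baseline_rate")
  expect_error(sim_config(weather = list(temp_mean = 8, temp_amplitude = 12,
                                         temp_sd = 3, rh_mean = 150,
                                         rh_sd = 10)),
               "rh_mean")
  bad <- default_pollutant_params()
  bad$NO2$ar <- 1.2
  expect_error(sim_config(pollutants = bad), "AR\\(1\\)")
  bad$NO2$ar <- 0.5; bad$NO2$sd <- -1
  expect_error(sim_config(pollutants = bad), ">= 0")
  expect_error(sim_config(effect = list(pollutant = "NO2", lag = 20,
                                        beta = 0)), "lag")
})

test_that("noise-free degenerate pollutant series is the pure seasonal mean", {
  cfg <- sim_config(n_days = 90, seed = 1, pollutants = list(
    X = list(mean = 10, amplitude = 0, phase = 0, ar = 0, sd = 0,
             units = "ppb")))
  s <- simulate_pollutants(cfg)$X
  expect_equal(s$value, rep(10, 90))
  expect_equal(nrow(s), 90L)
})

test_that("identical seeds reproduce byte-identical series; different seeds differ", {
  a1 <- simulate_pollutants(sim_config(n_days = 120, seed = 1))
  a2 <- simulate_pollutants(sim_config(n_days = 120, seed = 1))
  b <- simulate_pollutants(sim_config(n_days = 120, seed = 2))
  expect_identical(a1, a2)
  expect_false(identical(a1$NO2$value, b$NO2$value))

  w1 <- simulate_weather(sim_config(n_days = 120, seed = 3))
  w2 <- simulate_weather(sim_config(n_days = 120, seed = 3))
  expect_identical(w1, w2)

  cfg <- quick_sim_config(9, beta = 0.01)
  p <- simulate_pollutants(cfg); w <- simulate_weather(cfg)
  c1 <- simulate_counts(cfg, p$NO2, w)
  c2 <- simulate_counts(cfg, p$NO2, w)
  expect_identical(c1$count, c2$count)
})

test_that("pollutant series are non-negative and AR(1) autocorrelation is recovered", {
  cfg <- sim_config(n_days = 10000, seed = 4, pollutants = list(
    X = list(mean = 50, amplitude = 0, phase = 0, ar = 0.6, sd = 1,
             units = "ppb")))
  s <- simulate_pollutants(cfg)$X
  expect_true(all(s$value >= 0))
  # no seasonality configured, so the series is mean + AR(1) noise;
  # oracle: direct sample lag-1 autocorrelation
  e <- s$value - 50
  r1 <- stats::cor(e[-1], e[-length(e)])
  expect_lt(abs(r1 - 0.6), 0.05)

  # defaults stay non-negative too
  for (ser in simulate_pollutants(sim_config(n_days = 2000, seed = 5)))
    expect_true(all(ser$value >= 0, na.rm = TRUE))
})

test_that("weather respects bounds and the noise-free sinusoid has full amplitude", {
  cfg <- sim_config(n_days = 3650, seed = 6,
                    weather = list(temp_mean = 8, temp_amplitude = 12,
                                   temp_sd = 0, rh_mean = 70, rh_sd = 25))
  w <- simulate_weather(cfg)
  expect_true(all(w$rh >= 0 & w$rh <= 100))
  expect_equal(max(w$temp) - min(w$temp), 24, tolerance = 0.01)
})

test_that("homogeneous null counts match the analytic Poisson mean", {
  cfg <- sim_config(n_days = 10000, seed = 8,
                    pollutants = default_pollutant_params()["NO2"],
                    effect = list(pollutant = "NO2", lag = 0, beta = 0),
                    baseline_rate = 20, dow_effects = rep(1, 7),
                    temp_effect = c(0, 0), rh_effect = c(0, 0),
                    month_sd = 0)
  p <- simulate_pollutants(cfg); w <- simulate_weather(cfg)
  cnt <- simulate_counts(cfg, p$NO2, w)
  # oracle: mean of a homogeneous Poisson(20); MC tolerance 3*sqrt(20/n)
  expect_lt(abs(mean(cnt$count) - 20), 3 * sqrt(20 / nrow(cnt)))
})

test_that("a planted log-linear effect shifts the rate by exp(beta * dx)", {
  base <- list(
    pollutants = list(X = list(mean = 0, amplitude = 0, phase = 0, ar = 0,
                               sd = 0, units = "ppb")),
    effect = list(pollutant = "X", lag = 0, beta = 0.05),
    baseline_rate = 20, dow_effects = rep(1, 7),
    temp_effect = c(0, 0), rh_effect = c(0, 0), month_sd = 0)
  run <- function(level, seed) {
    cfg <- base
    cfg$pollutants$X$mean <- level
    cfg <- do.call(sim_config, c(cfg, list(n_days = 8000, seed = seed)))
    p <- simulate_pollutants(cfg); w <- simulate_weather(cfg)
    mean(simulate_counts(cfg, p$X, w)$count)
  }
  ratio <- run(10, 21) / run(0, 22)
  # oracle: closed-form rate ratio exp(0.05 * 10) = exp(0.5)
  se_ratio <- exp(0.5) * sqrt(2 / (8000 * 20)) * 3
  expect_lt(abs(ratio - exp(0.5)), 5 * se_ratio)
})

test_that("missingness injection removes roughly the configured fraction", {
  cfg <- sim_config(n_days = 5000, seed = 10, missing_rate = 0.1,
                    pollutants = default_pollutant_params()["NO2"])
  s <- simulate_pollutants(cfg)$NO2
  frac <- mean(is.na(s$value))
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 5000))
})

test_that("multinomial split preserves daily chapter totals and stratum additivity", {
  cnt <- data.frame(date = as.Date("2005-01-01") + 0:199,
                    count = rpois(200, 50))
  sp <- split_counts(cnt, seed = 3)
  daily <- tapply(sp$count, sp$date, sum)
  expect_equal(as.numeric(daily), cnt$count)

  ps <- enumerate_patient_strata()
  all_s <- stratum_counts(sp, ps[ps$label == "All", ])
  fem <- stratum_counts(sp, ps[ps$label == "Female", ])
  mal <- stratum_counts(sp, ps[ps$label == "Male", ])
  expect_equal(fem$count + mal$count, all_s$count)

  warm <- stratum_counts(sp, ps[ps$label == "Warm all", ])
  cold <- stratum_counts(sp, ps[ps$label == "Cold all", ])
  expect_equal(sort(c(warm$date, cold$date)), sort(all_s$date))
  expect_equal(sum(warm$count) + sum(cold$count), sum(all_s$count))

  ages <- lapply(c("Age 0-10 all", "Age 11-60 all", "Age 60+ all"),
                 function(l) stratum_counts(sp, ps[ps$label == l, ]))
  expect_equal(Reduce(`+`, lapply(ages, `[[`, "count")), all_s$count)
})

test_that("simulation bundles round-trip through CSV plus JSON metadata", {
  cfg <- quick_sim_config(12, beta = 0.02, n_days = 90)
  p <- simulate_pollutants(cfg); w <- simulate_weather(cfg)
  cnt <- simulate_counts(cfg, p$NO2, w)
  dir <- withr::local_tempdir()
  write_simulation(dir, cfg, p, w, cnt)
  back <- read_daily_series(file.path(dir, "pollutant_NO2.csv"), "NO2")
  expect_equal(back$value, p$NO2$value)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$rng, "Mersenne-Twister")
  expect_equal(meta$seed, 12L)
  expect_equal(meta$truth$beta, 0.02)
  counts_back <- utils::read.csv(file.path(dir, "counts.csv"))
  expect_equal(counts_back$count, cnt$count)
})
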
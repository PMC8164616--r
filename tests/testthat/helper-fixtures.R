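# shared fixture builders: every fixture is generated in code

## a single-pollutant simulation config with no weather confounding,
## sized for fast repeated fitting
quick_sim_config <- function(seed, beta = 0, lag = 0, n_days = 1000,
                             baseline_rate = 20, temp_effect = c(0, 0),
                             rh_effect = c(0, 0), ...) {
  sim_config(n_days = n_days, seed = seed,
             pollutants = default_pollutant_params()["NO2"],
             effect = list(pollutant = "NO2", lag = lag, beta = beta),
             baseline_rate = baseline_rate,
             temp_effect = temp_effect, rh_effect = rh_effect, ...)
}

## simulate, assemble and fit one replicate; returns the cc_fit
simulate_and_fit <- function(seed, beta = 0, lag = 0, n_days = 1000,
                             spline_df = 0, ...) {
  cfg <- quick_sim_config(seed, beta, lag, n_days, ...)
  pol <- simulate_pollutants(cfg)
  w <- simulate_weather(cfg)
  cnt <- simulate_counts(cfg, pol$NO2, w)
  ds <- build_cc_dataset(cnt, pol$NO2, w, lag = lag, spline_df = spline_df)
  fit_conditional_poisson(ds)
}

## independent oracle for the conditional fit: unconditional Poisson
## regression with one indicator per time stratum
glm_dummy_oracle <- function(dataset) {
  df <- as.data.frame(dataset)
  covs <- setdiff(names(df), c("date", "count", "stratum"))
  f <- stats::as.formula(paste("count ~", paste(covs, collapse = " + "),
                               "+ factor(stratum)"))
  g <- stats::glm(f, family = stats::poisson, data = df)
  list(beta = stats::coef(g)[["exposure"]],
       se = sqrt(diag(stats::vcov(g)))[["exposure"]])
}

## brute-force daily maximum 8-h mean over all 17 candidate windows
brute_max_8h <- function(values24, min_hours = 6) {
  best <- NA_real_
  for (s in 0:16) {
    w <- values24[(s + 1):(s + 8)]
    if (sum(!is.na(w)) >= min_hours) {
      m <- mean(w, na.rm = TRUE)
      if (is.na(best) || m > best) best <- m
    }
  }
  best
}

## tiny two-month count/exposure/weather fixture on a fixed seed
tiny_series <- function(seed = 42, n_days = 120) {
  cfg <- quick_sim_config(seed, beta = 0.01, lag = 0, n_days = n_days)
  list(config = cfg,
       pollutants = simulate_pollutants(cfg),
       weather = simulate_weather(cfg))
}
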
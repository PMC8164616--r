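#' Simulation configuration
#'
#' Assembles and validates the configuration for the synthetic-data
#' generator: daily pollutant series (seasonal sinusoid plus AR(1)
#' noise, truncated at zero), daily weather (sinusoidal temperature,
#' truncated-Gaussian relative humidity) and daily event counts whose
#' log-rate contains a baseline, day-of-week factors, smooth weather
#' terms, month-level intercept shifts and a planted log-linear lagged
#' exposure effect.  With a fixed seed the generator is bit-identical
#' across runs (R's Mersenne-Twister stream, recorded in the output
#' metadata).
#'
#' @param n_days number of days to simulate (>= 60, so at least two
#'   calendar months of time strata exist).
#' @param start_date first simulated date.
#' @param seed integer RNG seed.
#' @param pollutants named list of per-pollutant parameter lists with
#'   elements `mean`, `amplitude`, `phase` (radians), `ar` (AR(1)
#'   coefficient in (-1, 1)), `sd` (innovation sd >= 0) and `units`;
#'   defaults emulate urban daily series for CO (ppm), NO2, O3, O3H8,
#'   SO2 (ppb) and PM2.5 (ug/m3).
#' @param weather list with `temp_mean`, `temp_amplitude`, `temp_sd`
#'   (degrees C) and `rh_mean`, `rh_sd` (percent, truncated to
#'   [0, 100]).
#' @param effect list with `pollutant` (name of the target exposure),
#'   `lag` (0-14) and `beta` (true log-rate slope per concentration
#'   unit).
#' @param baseline_rate expected daily count at reference covariates
#'   (> 0).
#' @param dow_effects 7 multiplicative day-of-week factors
#'   (Monday first).
#' @param temp_effect,rh_effect quadratic coefficients `c(linear,
#'   quadratic)` of the smooth log-rate weather terms, centred at
#'   `temp_ref`/`rh_ref`; confounding strength is deliberately a free
#'   parameter.
#' @param temp_ref,rh_ref centring constants of the weather terms.
#' @param month_sd sd of independent Gaussian month-level log-rate
#'   shifts (absorbed by the time strata during estimation).
#' @param missing_rate i.i.d. Bernoulli deletion rate for pollutant
#'   values (0 disables missingness).
#' @param sex_age_proportions named numeric vector over the 6 sex-age
#'   cells (`female.0-10`, ..., `male.61+`), summing to 1, used by
#'   [split_counts()].
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_days = 730L,
                       start_date = "2004-04-01",
                       seed = 1L,
                       pollutants = default_pollutant_params(),
                       weather = list(temp_mean = 8, temp_amplitude = 12,
                                      temp_sd = 3, rh_mean = 70, rh_sd = 10),
                       effect = list(pollutant = "NO2", lag = 0L, beta = 0),
                       baseline_rate = 100,
                       dow_effects = c(1.08, 1.0, 0.98, 0.97, 1.0, 0.93, 0.9),
                       temp_effect = c(0, 2e-4),
                       rh_effect = c(0, 0),
                       temp_ref = 10,
                       rh_ref = 70,
                       month_sd = 0.05,
                       missing_rate = 0,
                       sex_age_proportions = default_sex_age_proportions()) {
  if (!is_scalar_number(n_days) || n_days < 60)
    stopf("n_days must be >= 60 (got %s)", format(n_days))
  if (!is_scalar_number(seed) || seed != round(seed))
    stopf("seed must be a single integer")
  for (nm in names(pollutants)) {
    p <- pollutants[[nm]]
    if (!is_scalar_number(p$ar) || abs(p$ar) >= 1)
      stopf("pollutant %s: AR(1) coefficient must lie in (-1, 1)", nm)
    if (p$sd < 0 || p$amplitude < 0 || p$mean < 0)
      stopf("pollutant %s: mean, amplitude and sd must be >= 0", nm)
  }
  if (weather$temp_sd < 0 || weather$rh_sd < 0)
    stopf("weather sds must be >= 0")
  if (weather$rh_mean < 0 || weather$rh_mean > 100)
    stopf("rh_mean must lie in [0, 100] (got %s)", format(weather$rh_mean))
  if (effect$lag < 0 || effect$lag > 14)
    stopf("effect lag must be in 0..14")
  if (!is_scalar_number(baseline_rate) || baseline_rate <= 0)
    stopf("baseline_rate must be > 0")
  if (length(dow_effects) != 7L || any(dow_effects <= 0))
    stopf("dow_effects must be 7 positive factors")
  if (missing_rate < 0 || missing_rate >= 1)
    stopf("missing_rate must lie in [0, 1)")
  if (abs(sum(sex_age_proportions) - 1) > 1e-8)
    stopf("sex_age_proportions must sum to 1")
  cfg <- list(n_days = as.integer(n_days),
              start_date = as_iso_date(start_date, "start_date"),
              seed = as.integer(seed), pollutants = pollutants,
              weather = weather, effect = effect,
              baseline_rate = baseline_rate, dow_effects = dow_effects,
              temp_effect = temp_effect, rh_effect = rh_effect,
              temp_ref = temp_ref, rh_ref = rh_ref, month_sd = month_sd,
              missing_rate = missing_rate,
              sex_age_proportions = sex_age_proportions,
              rng = "Mersenne-Twister")
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_pollutant_params <- function() {
  list(
    CO   = list(mean = 0.4, amplitude = 0.08, phase = 3.6, ar = 0.6,
                sd = 0.08, units = "ppm"),
    NO2  = list(mean = 20, amplitude = 5, phase = 3.6, ar = 0.6,
                sd = 4, units = "ppb"),
    O3   = list(mean = 25, amplitude = 10, phase = 0.5, ar = 0.55,
                sd = 6, units = "ppb"),
    O3H8 = list(mean = 32, amplitude = 12, phase = 0.5, ar = 0.55,
                sd = 7, units = "ppb"),
    SO2  = list(mean = 2.5, amplitude = 0.8, phase = 3.6, ar = 0.5,
                sd = 1, units = "ppb"),
    PM25 = list(mean = 8, amplitude = 2.5, phase = 0.9, ar = 0.5,
                sd = 3, units = "ug/m3"))
}

#' @rdname sim_config
#' @export
default_sex_age_proportions <- function() {
  # sex split 50/50; age split 15/60/25 within sex
  p <- c(`female.0-10` = 0.075, `female.11-60` = 0.30, `female.61+` = 0.125,
         `male.0-10` = 0.075, `male.11-60` = 0.30, `male.61+` = 0.125)
  p / sum(p)
}

sim_dates <- function(config) config$start_date + seq_len(config$n_days) - 1L

seasonal <- function(dates, mean, amplitude, phase) {
  doy <- as.integer(format(dates, "%j"))
  mean + amplitude * sin(2 * pi * doy / 365.25 + phase)
}

#' Simulate daily pollutant series
#'
#' One series per configured pollutant:
#' `value_t = max(0, seasonal_t + e_t)` where `seasonal_t` is a
#' sinusoid with a 365.25-day period and `e_t` is stationary AR(1)
#' noise.  Missing days (if `missing_rate > 0`) are deleted i.i.d.
#'
#' @param config a [sim_config()].
#' @return named list of [exposure_series()], one per pollutant.
#' @export
simulate_pollutants <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dates <- sim_dates(config)
  n <- config$n_days
  withr_seed(config$seed, "pollutants", {
    out <- lapply(names(config$pollutants), function(nm) {
      p <- config$pollutants[[nm]]
      e <- numeric(n)
      if (p$sd > 0) {
        # stationary start so the marginal variance is constant
        e[1] <- stats::rnorm(1, 0, p$sd / sqrt(1 - p$ar^2))
        innov <- stats::rnorm(n - 1, 0, p$sd)
        for (t in 2:n) e[t] <- p$ar * e[t - 1] + innov[t - 1]
      }
      v <- pmax(0, seasonal(dates, p$mean, p$amplitude, p$phase %||% 0) + e)
      if (config$missing_rate > 0)
        v[stats::runif(n) < config$missing_rate] <- NA_real_
      exposure_series(dates, v, nm, p$units %||% "")
    })
    names(out) <- names(config$pollutants)
    out
  })
}

#' Simulate daily weather
#'
#' Temperature is a seasonal sinusoid plus Gaussian noise; relative
#' humidity is Gaussian around its mean, truncated to [0, 100].
#'
#' @param config a [sim_config()].
#' @return data frame with columns `date`, `temp` (degrees C) and `rh`
#'   (percent).
#' @export
simulate_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dates <- sim_dates(config)
  w <- config$weather
  withr_seed(config$seed, "weather", {
    temp <- seasonal(dates, w$temp_mean, w$temp_amplitude, -pi / 2 + 0.45) +
      stats::rnorm(config$n_days, 0, w$temp_sd)
    rh <- pmin(100, pmax(0, stats::rnorm(config$n_days, w$rh_mean, w$rh_sd)))
    data.frame(date = dates, temp = temp, rh = rh)
  })
}

planted_log_rate <- function(config, exposure, weather) {
  dates <- sim_dates(config)
  idx <- match(dates, exposure$date)
  if (anyNA(idx))
    stopf("exposure does not cover the simulated date range")
  lagged <- lag_series(exposure[idx, , drop = FALSE], config$effect$lag)
  widx <- match(dates, weather$date)
  if (anyNA(widx))
    stopf("weather does not cover the simulated date range")
  wl <- weather[widx, , drop = FALSE]
  if (config$effect$lag > 0) {
    k <- config$effect$lag
    wl$temp <- c(rep(NA_real_, k), wl$temp[seq_len(nrow(wl) - k)])
    wl$rh <- c(rep(NA_real_, k), wl$rh[seq_len(nrow(wl) - k)])
  }
  dow <- as.integer(format(dates, "%u"))
  s_temp <- config$temp_effect[1] * (wl$temp - config$temp_ref) +
    config$temp_effect[2] * (wl$temp - config$temp_ref)^2
  s_rh <- config$rh_effect[1] * (wl$rh - config$rh_ref) +
    config$rh_effect[2] * (wl$rh - config$rh_ref)^2
  month_key <- format(dates, "%Y-%m")
  months <- unique(month_key)
  shifts <- withr_seed(config$seed, "months", {
    stats::setNames(stats::rnorm(length(months), 0, config$month_sd), months)
  })
  eta <- log(config$baseline_rate) + log(config$dow_effects[dow]) +
    config$effect$beta * lagged$value + s_temp + s_rh +
    shifts[month_key]
  list(dates = dates, eta = as.numeric(eta), month_shifts = shifts,
       dropped = sum(is.na(eta)))
}

#' Simulate daily event counts with a planted exposure effect
#'
#' Draws `count_t ~ Poisson(mu_t)` with
#' `log mu_t = log(baseline) + log(dow factor) + beta * x_{t-lag} +
#' s(temp_{t-lag}) + s(rh_{t-lag}) + month shift`, where `s(.)` are the
#' configured smooth quadratic weather terms and the month-level shifts
#' emulate the slow variation that the time-stratified design absorbs.
#' Days whose lagged exposure falls before the start of the exposure
#' series are dropped (their number is recorded in the attributes).
#'
#' @param config a [sim_config()].
#' @param exposure an [exposure_series()] for the effect's target
#'   pollutant, covering the simulated date range.
#' @param weather a weather data frame as from [simulate_weather()].
#' @return data frame of class `count_series` with columns `date` and
#'   `count`, and attributes `truth` (planted parameters) and
#'   `n_dropped`.
#' @export
simulate_counts <- function(config, exposure, weather) {
  stopifnot(inherits(config, "sim_config"))
  pl <- planted_log_rate(config, exposure, weather)
  keep <- !is.na(pl$eta)
  counts <- withr_seed(config$seed, "counts", {
    stats::rpois(sum(keep), exp(pl$eta[keep]))
  })
  out <- data.frame(date = pl$dates[keep], count = counts)
  attr(out, "truth") <- list(
    beta = config$effect$beta, lag = config$effect$lag,
    pollutant = config$effect$pollutant,
    baseline_rate = config$baseline_rate,
    dow_effects = config$dow_effects,
    temp_effect = config$temp_effect, rh_effect = config$rh_effect,
    temp_ref = config$temp_ref, rh_ref = config$rh_ref,
    month_shifts = pl$month_shifts, rng = config$rng)
  attr(out, "n_dropped") <- pl$dropped
  class(out) <- c("count_series", "data.frame")
  out
}

#' Split a daily count series into sex-age cells
#'
#' Divides each day's total count across the 6 sex-by-age cells by a
#' multinomial draw with fixed proportions, so subgroup counts sum
#' exactly to the chapter total on every day and the additive structure
#' of the patient strata holds by construction (season follows from the
#' date).
#'
#' @param counts a count series (`date`, `count`).
#' @param proportions named proportions over the 6 cells; see
#'   [default_sex_age_proportions()].
#' @param seed integer seed for the multinomial split.
#' @return data frame in long format: `date`, `sex`, `age`, `count`.
#' @export
split_counts <- function(counts, proportions = default_sex_age_proportions(),
                         seed = 1L) {
  if (abs(sum(proportions) - 1) > 1e-8)
    stopf("proportions must sum to 1")
  cells <- strsplit(names(proportions), ".", fixed = TRUE)
  sex <- vapply(cells, `[`, "", 1L)
  age <- vapply(cells, `[`, "", 2L)
  mat <- withr_seed(seed, "split", {
    vapply(counts$count, function(y)
      as.numeric(stats::rmultinom(1, y, proportions)),
      numeric(length(proportions)))
  })
  data.frame(date = rep(counts$date, each = length(proportions)),
             sex = rep(sex, nrow(counts)), age = rep(age, nrow(counts)),
             count = as.integer(mat))
}

#' Aggregate split counts to one patient stratum
#'
#' Filters the long sex-age-day counts to the stratum's season (by
#' date) and sums the matching sex-age cells per day.
#'
#' @param split_df long data frame from [split_counts()].
#' @param stratum one row of [enumerate_patient_strata()].
#' @return count series data frame (`date`, `count`) restricted to the
#'   stratum's season.
#' @export
stratum_counts <- function(split_df, stratum) {
  keep <- rep(TRUE, nrow(split_df))
  if (stratum$sex != "all") keep <- keep & split_df$sex == stratum$sex
  if (stratum$age != "all") keep <- keep & split_df$age == stratum$age
  x <- split_df[keep, , drop = FALSE]
  agg <- stats::aggregate(count ~ date, data = x, FUN = sum)
  agg <- agg[order(agg$date), , drop = FALSE]
  if (stratum$season != "all")
    agg <- agg[assign_season(agg$date) == stratum$season, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Write a simulated dataset to disk
#'
#' Writes each pollutant series, the weather series and the count
#' series as CSV (ISO-8601 dates, missing values empty) plus a JSON
#' sidecar recording the configuration, seed, RNG algorithm and planted
#' truth.
#'
#' @param dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param pollutants result of [simulate_pollutants()].
#' @param weather result of [simulate_weather()].
#' @param counts result of [simulate_counts()] (optional).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dir, config, pollutants, weather,
                             counts = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(pollutants))
    write_daily_series(pollutants[[nm]],
                       file.path(dir, paste0("pollutant_", nm, ".csv")))
  utils::write.csv(
    data.frame(date = format(weather$date), temp = weather$temp,
               rh = weather$rh),
    file.path(dir, "weather.csv"), row.names = FALSE, na = "")
  meta <- list(config = unclass(config), rng = config$rng,
               seed = config$seed)
  if (!is.null(counts)) {
    utils::write.csv(
      data.frame(date = format(counts$date), count = counts$count),
      file.path(dir, "counts.csv"), row.names = FALSE, na = "")
    meta$truth <- attr(counts, "truth")
  }
  meta$config$start_date <- format(config$start_date)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

## run expr under a seed derived deterministically from (seed, label)
## without disturbing the caller's RNG state
withr_seed <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  offset <- sum(utf8ToInt(label)) * 10007L
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max,
           kind = "Mersenne-Twister")
  force(expr)
}
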
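#' Construct a daily exposure series
#'
#' A light container for one pollutant or composite index: a data frame
#' with a `date` column (class `Date`, strictly increasing, daily
#' resolution) and a `value` column (non-negative where observed, `NA`
#' for missing days), carrying the pollutant identifier and unit label
#' as attributes.
#'
#' @param dates vector of dates (`Date` or ISO-8601 strings), strictly
#'   increasing.
#' @param values numeric vector of daily concentrations, same length as
#'   `dates`; `NA` marks a missing day.
#' @param pollutant identifier, e.g. `"NO2"`, `"PM25"`, `"AQHI"`.
#' @param units unit label, e.g. `"ppb"`, `"ug/m3"`; composite indices
#'   are dimensionless (`"index"`).
#' @return a `data.frame` of class `exposure_series` with columns
#'   `date` and `value`.
#' @examples
#' exposure_series(as.Date("2005-01-01") + 0:2, c(10, 12, NA), "NO2", "ppb")
#' @export
exposure_series <- function(dates, values, pollutant, units = "") {
  dates <- check_daily_dates(dates, "exposure series")
  if (length(values) != length(dates))
    stopf("values and dates differ in length (%d vs %d)",
          length(values), length(dates))
  values <- as.numeric(values)
  if (any(values < 0, na.rm = TRUE))
    stopf("exposure values must be non-negative (pollutant %s)", pollutant)
  out <- data.frame(date = dates, value = values)
  attr(out, "pollutant") <- as.character(pollutant)
  attr(out, "units") <- as.character(units)
  class(out) <- c("exposure_series", "data.frame")
  out
}

#' Default AQHI risk coefficients
#'
#' Per-pollutant excess-mortality coefficients and the overall scaling
#' used by the Canadian Air Quality Health Index.  The three
#' coefficients multiply NO2 (ppb), O3 (ppb) and PM2.5 (ug/m3) inside
#' the exponential risk terms; the index is scaled by 10/10.4 x 100 so
#' that typical urban mixtures land on the familiar 1-10 band.
#'
#' @return list with elements `no2`, `o3`, `pm25` (per-unit
#'   coefficients) and `scale`.
#' @export
aqhi_coefficients <- function() {
  list(no2 = 0.000871, o3 = 0.000537, pm25 = 0.000487,
       scale = 10 / 10.4 * 100)
}

#' Air Quality Health Index from its three constituents
#'
#' Computes the continuous (unrounded) AQHI
#' \deqn{AQHI = \frac{10}{10.4} \times 100 \times
#'   [(e^{c_1 NO_2} - 1) + (e^{c_2 O_3} - 1) + (e^{c_3 PM_{2.5}} - 1)]}
#' from same-day NO2, O3 and PM2.5.  The index is returned on its
#' continuous scale, not rounded to the operational integer bands,
#' since it is used here as a regression exposure.
#'
#' @param no2 NO2 in ppb.
#' @param o3 O3 in ppb.
#' @param pm25 PM2.5 in ug/m3.
#' @param coefficients coefficient list as from [aqhi_coefficients()].
#' @return numeric vector; `NA` wherever any constituent is missing.
#' @examples
#' compute_aqhi(20, 30, 10)
#' @export
compute_aqhi <- function(no2, o3, pm25, coefficients = aqhi_coefficients()) {
  n <- max(length(no2), length(o3), length(pm25))
  no2 <- rep_len(as.numeric(no2), n)
  o3 <- rep_len(as.numeric(o3), n)
  pm25 <- rep_len(as.numeric(pm25), n)
  if (any(c(no2, o3, pm25) < 0, na.rm = TRUE))
    stopf("AQHI constituents must be non-negative")
  coefficients$scale *
    ((exp(coefficients$no2 * no2) - 1) +
     (exp(coefficients$o3 * o3) - 1) +
     (exp(coefficients$pm25 * pm25) - 1))
}

#' AQHIX: the AQHI with daily maximum 8-h ozone
#'
#' Identical to [compute_aqhi()] except that the ozone term uses the
#' daily maximum 8-h running mean (O3H8) in place of the daily mean O3,
#' emphasising ozone peaks in the multi-pollutant mixture.
#'
#' @param no2 NO2 in ppb.
#' @param o3h8 daily maximum 8-h ozone in ppb.
#' @param pm25 PM2.5 in ug/m3.
#' @param coefficients coefficient list as from [aqhi_coefficients()].
#' @return numeric vector; `NA` wherever any constituent is missing.
#' @export
compute_aqhix <- function(no2, o3h8, pm25, coefficients = aqhi_coefficients()) {
  compute_aqhi(no2, o3h8, pm25, coefficients)
}

#' Daily maximum 8-h running mean from hourly data
#'
#' For each calendar day, the maximum over running 8-hour window means
#' with window start hours 00:00 through 16:00 (17 windows, each fully
#' inside the day).  A window is valid when at least `min_hours` of its
#' 8 hours are observed; a day with no valid window is missing.  This
#' is the convention used to derive the O3H8 exposure metric.
#'
#' @param hourly data frame with columns `date` (ISO-8601), `hour`
#'   (integer 0-23) and `value`; at most one row per date-hour.
#' @param min_hours minimum observed hours for a valid window
#'   (default 6 of 8).
#' @return data frame with columns `date` and `value` (the daily
#'   maximum 8-h mean, `NA` when no valid window exists), one row per
#'   date present in the input.
#' @examples
#' h <- data.frame(date = "2005-06-01", hour = 0:23, value = 1:24)
#' daily_max_8h(h) # mean of hours 16..23 = 20.5
#' @export
daily_max_8h <- function(hourly, min_hours = 6L) {
  need <- c("date", "hour", "value")
  if (!is.data.frame(hourly) || !all(need %in% names(hourly)))
    stopf("hourly input needs columns date, hour, value")
  hour <- as.integer(hourly$hour)
  if (anyNA(hour) || any(hour < 0L | hour > 23L))
    stopf("hour must be an integer in 0..23: input is not hourly resolution")
  date <- as_iso_date(hourly$date, "hourly series date")
  if (anyDuplicated(paste(date, hour)))
    stopf("duplicated date-hour rows: input is not hourly resolution")
  value <- as.numeric(hourly$value)

  days <- sort(unique(date))
  out <- vapply(days, function(d) {
    v <- rep(NA_real_, 24L)
    sel <- date == d
    v[hour[sel] + 1L] <- value[sel]
    best <- NA_real_
    for (s in 0:16) {
      w <- v[(s + 1L):(s + 8L)]
      k <- sum(!is.na(w))
      if (k >= min_hours) {
        m <- mean(w, na.rm = TRUE)
        if (is.na(best) || m > best) best <- m
      }
    }
    best
  }, numeric(1))
  data.frame(date = days, value = out)
}

#' Lag a daily series by whole days
#'
#' Shifts values so that the value reported on date `d` is the original
#' value on `d - lag`; dates are unchanged and the first `lag` days
#' become missing.  Exposure and weather confounders are lagged by the
#' same number of days when building model datasets.
#'
#' @param series an [exposure_series()] or any data frame with `date`
#'   and `value` columns.
#' @param lag integer number of days, 0 to 14; lag 0 is the identity.
#' @return the series with shifted values (same class and attributes).
#' @export
lag_series <- function(series, lag) {
  if (!is.data.frame(series) || !all(c("date", "value") %in% names(series)))
    stopf("series must have date and value columns")
  if (!is_scalar_number(lag) || lag != round(lag) || lag < 0 || lag > 14)
    stopf("lag must be a single integer in 0..14 (got %s)", format(lag))
  lag <- as.integer(lag)
  n <- nrow(series)
  if (lag > 0L && n > 0L) {
    v <- series$value
    series$value <- c(rep(NA_real_, min(lag, n)),
                      v[seq_len(max(0L, n - lag))])
  }
  series
}

#' Read or write a daily series as CSV
#'
#' Plain-text interchange for daily series: two columns, `date`
#' (ISO-8601) and `value`, missing values as empty fields.
#'
#' @param path file path.
#' @param pollutant,units passed to [exposure_series()] when reading.
#' @return `read_daily_series()` returns an [exposure_series()];
#'   `write_daily_series()` returns `path` invisibly.
#' @export
read_daily_series <- function(path, pollutant = "", units = "") {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "value") %in% names(x)))
    stopf("%s: expected columns date,value", path)
  exposure_series(x$date, x$value, pollutant, units)
}

#' @rdname read_daily_series
#' @param series data frame with `date` and `value` columns.
#' @export
write_daily_series <- function(series, path) {
  utils::write.csv(
    data.frame(date = format(series$date), value = series$value),
    path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an hourly series from CSV
#'
#' Expects columns `date` (ISO-8601), `hour` (0-23) and `value`;
#' missing values as empty fields.
#'
#' @param path file path.
#' @return data frame with columns `date`, `hour`, `value`.
#' @export
read_hourly_series <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "hour", "value") %in% names(x)))
    stopf("%s: expected columns date,hour,value", path)
  x$date <- as_iso_date(x$date, "hourly date")
  x
}
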
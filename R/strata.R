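#' Time-stratified referent strata
#'
#' Maps each date to its case-crossover time stratum, the calendar
#' cluster "year: month: day of week".  All days sharing a year, month
#' and weekday form one stratum (4 or 5 days), so each event day is
#' compared only with referent days of the same weekday within the same
#' month, removing long-term trend, seasonality and weekday patterns by
#' design.  Weekday numbering is ISO-8601 (Monday = 1).
#'
#' @param dates vector of dates (`Date` or ISO-8601 strings).
#' @return data frame with one row per input date: `date`, `year`,
#'   `month`, `day_of_week` and the stratum `key` (a string
#'   `"YYYY:MM:W"`).
#' @examples
#' build_time_strata(as.Date("2004-04-05") + c(0, 7, 1))
#' @export
build_time_strata <- function(dates) {
  dates <- as_iso_date(dates, "dates")
  year <- as.integer(format(dates, "%Y"))
  month <- as.integer(format(dates, "%m"))
  # ISO weekday: Monday = 1 .. Sunday = 7
  dow <- as.integer(format(dates, "%u"))
  data.frame(date = dates, year = year, month = month, day_of_week = dow,
             key = sprintf("%04d:%02d:%d", year, month, dow),
             stringsAsFactors = FALSE)
}

#' Season of a date
#'
#' Warm season is April through September; cold season is October
#' through March.
#'
#' @param dates vector of dates (`Date` or ISO-8601 strings).
#' @return character vector, `"warm"` or `"cold"`.
#' @examples
#' assign_season(c("2005-04-01", "2005-10-01"))
#' @export
assign_season <- function(dates) {
  m <- as.integer(format(as_iso_date(dates, "dates"), "%m"))
  ifelse(m >= 4L & m <= 9L, "warm", "cold")
}

#' Enumerate the 18 patient strata
#'
#' The analysis is repeated over 18 population subgroups defined by
#' sex (all, female, male), season (all, warm, cold) and age group
#' (all, 0-10, 11-60, 61+): the 3 sex-only strata, the 6 season-by-sex
#' strata and the 9 age-by-sex strata, in that fixed order.  Age and
#' season are never crossed.
#'
#' The default elderly band starts at 61 ("Age 60+" is retained as the
#' conventional row label); the cut points are configurable via
#' `age_breaks`, upper bounds inclusive for the first two bands.
#'
#' @param age_breaks two increasing integer upper bounds giving the age
#'   bands `[0, b1]`, `[b1+1, b2]`, `[b2+1, Inf)`; default `c(10, 60)`.
#' @return data frame with 18 rows and columns `label`, `sex`
#'   (`all`/`female`/`male`), `age` (`all` or a band label) and
#'   `season` (`all`/`warm`/`cold`).
#' @export
enumerate_patient_strata <- function(age_breaks = c(10L, 60L)) {
  if (length(age_breaks) != 2L || any(diff(age_breaks) <= 0))
    stopf("age_breaks must be two increasing values")
  b1 <- age_breaks[1]; b2 <- age_breaks[2]
  bands <- c(sprintf("%d-%d", 0L, b1), sprintf("%d-%d", b1 + 1L, b2),
             sprintf("%d+", b2 + 1L))
  sexes <- c("all", "female", "male")
  sex_cap <- c(all = "All", female = "Female", male = "Male")

  rows <- list()
  for (s in sexes)
    rows[[length(rows) + 1L]] <- data.frame(
      label = sex_cap[[s]], sex = s, age = "all", season = "all")
  for (season in c("warm", "cold"))
    for (s in sexes)
      rows[[length(rows) + 1L]] <- data.frame(
        label = paste(tools::toTitleCase(season), s), sex = s,
        age = "all", season = season)
  # conventional row labels: "Age 0-10", "Age 11-60", "Age 60+"
  band_labels <- c(bands[1], bands[2], sprintf("%d+", b2))
  for (i in seq_along(bands))
    for (s in sexes)
      rows[[length(rows) + 1L]] <- data.frame(
        label = paste0("Age ", band_labels[i], " ", s), sex = s,
        age = bands[i], season = "all")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(nrow(out) == 18L)
  out
}

#' Age band of an age in years
#'
#' @param age integer ages in years.
#' @param age_breaks as in [enumerate_patient_strata()].
#' @return character vector of band labels matching the `age` column of
#'   [enumerate_patient_strata()].
#' @export
assign_age_band <- function(age, age_breaks = c(10L, 60L)) {
  b1 <- age_breaks[1]; b2 <- age_breaks[2]
  bands <- c(sprintf("%d-%d", 0L, b1), sprintf("%d-%d", b1 + 1L, b2),
             sprintf("%d+", b2 + 1L))
  ifelse(age <= b1, bands[1], ifelse(age <= b2, bands[2], bands[3]))
}

#' Export stratum definitions to CSV
#'
#' @param path file path.
#' @param age_breaks as in [enumerate_patient_strata()].
#' @return `path`, invisibly.
#' @export
write_patient_strata <- function(path, age_breaks = c(10L, 60L)) {
  utils::write.csv(enumerate_patient_strata(age_breaks), path,
                   row.names = FALSE)
  invisible(path)
}
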
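# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## coerce to Date, failing loudly on anything that does not parse as ISO-8601
as_iso_date <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d) && !anyNA(x))
    stopf("%s must be ISO-8601 (YYYY-MM-DD); failed to parse %s",
          what, paste(utils::head(x[is.na(d)], 3), collapse = ", "))
  d
}

check_daily_dates <- function(dates, what = "series") {
  dates <- as_iso_date(dates, what)
  if (length(dates) > 1L) {
    dd <- diff(as.integer(dates))
    if (any(dd <= 0)) stopf("%s dates must be strictly increasing", what)
  }
  dates
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
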
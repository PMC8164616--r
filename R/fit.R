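#' Natural cubic spline basis
#'
#' Basis for the smooth temperature and relative-humidity adjustment
#' terms: a natural cubic spline with boundary knots at the observed
#' range and interior knots at equally spaced quantiles, linear beyond
#' the boundary knots.  A thin wrapper around [splines::ns()] that
#' enforces enough distinct values for the requested dimension.
#'
#' @param x numeric vector.
#' @param df number of basis columns (>= 1).
#' @return numeric matrix with `length(x)` rows and `df` columns; the
#'   knots are attached as attributes.
#' @export
natural_spline_basis <- function(x, df) {
  if (!is_scalar_number(df) || df < 1 || df != round(df))
    stopf("df must be a positive integer")
  x <- as.numeric(x)
  n_distinct <- length(unique(x[!is.na(x)]))
  if (n_distinct < df + 2)
    stopf("natural spline with df=%d needs >= %d distinct values (got %d)",
          df, df + 2, n_distinct)
  b <- splines::ns(x, df = df)
  m <- matrix(as.numeric(b), nrow = length(x), ncol = df)
  attr(m, "knots") <- as.numeric(attr(b, "knots"))
  attr(m, "boundary_knots") <- as.numeric(attr(b, "Boundary.knots"))
  m
}

#' Assemble a model-ready case-crossover dataset
#'
#' Joins daily counts with the exposure and weather series, lags
#' exposure, temperature and relative humidity by the same number of
#' days, drops incomplete rows (complete-case rule), attaches the
#' year-month-weekday time stratum of each date, and removes strata
#' that carry no information for the conditional likelihood (total
#' count zero, or fewer than two days).  Spline bases for the lagged
#' weather variables are computed on the retained rows.
#'
#' @param counts count series (`date`, `count`).
#' @param exposure an [exposure_series()] (or `date`/`value` data
#'   frame).
#' @param weather data frame with `date`, `temp`, `rh`.
#' @param lag single-day exposure lag, 0-14; weather is lagged
#'   identically.
#' @param spline_df natural-spline dimension per weather variable
#'   (default 3); `0` omits weather adjustment entirely.
#' @return data frame of class `cc_dataset` with columns `date`,
#'   `count`, `exposure`, `stratum`, and `temp_1..temp_df`,
#'   `rh_1..rh_df` spline columns when `spline_df > 0`.  Attributes
#'   record `lag`, `spline_df`, the dropped-row and dropped-stratum
#'   tallies and the spline knots.
#' @export
build_cc_dataset <- function(counts, exposure, weather, lag,
                             spline_df = 3L) {
  if (!is_scalar_number(spline_df) || spline_df < 0 ||
      spline_df != round(spline_df))
    stopf("spline_df must be a non-negative integer")
  lagged_x <- lag_series(data.frame(date = exposure$date,
                                    value = exposure$value), lag)
  lagged_w <- data.frame(date = weather$date,
                         temp = weather$temp, rh = weather$rh)
  if (lag > 0) {
    k <- as.integer(lag)
    shift <- function(v) c(rep(NA_real_, min(k, length(v))),
                           v[seq_len(max(0L, length(v) - k))])
    lagged_w$temp <- shift(lagged_w$temp)
    lagged_w$rh <- shift(lagged_w$rh)
  }
  d <- merge(data.frame(date = counts$date, count = counts$count),
             lagged_x, by = "date")
  d <- merge(d, lagged_w, by = "date")
  names(d)[names(d) == "value"] <- "exposure"
  n0 <- nrow(d)
  ok <- !is.na(d$count) & !is.na(d$exposure)
  if (spline_df > 0) ok <- ok & !is.na(d$temp) & !is.na(d$rh)
  d <- d[ok, , drop = FALSE]
  n_missing <- n0 - nrow(d)

  ts <- build_time_strata(d$date)
  d$stratum <- ts$key
  tot <- tapply(d$count, d$stratum, sum)
  nrows <- table(d$stratum)
  bad <- names(tot)[tot == 0 | nrows[names(tot)] < 2]
  n_stratum_rows <- sum(d$stratum %in% bad)
  d <- d[!d$stratum %in% bad, , drop = FALSE]
  if (nrow(d) == 0)
    stopf("no usable rows remain after complete-case and stratum filtering")

  knots <- list()
  if (spline_df > 0) {
    tb <- natural_spline_basis(d$temp, spline_df)
    rb <- natural_spline_basis(d$rh, spline_df)
    knots <- list(temp = attributes(tb)[c("knots", "boundary_knots")],
                  rh = attributes(rb)[c("knots", "boundary_knots")])
    colnames(tb) <- paste0("temp_", seq_len(spline_df))
    colnames(rb) <- paste0("rh_", seq_len(spline_df))
    d <- cbind(d[c("date", "count", "exposure", "stratum")], tb, rb)
  } else {
    d <- d[c("date", "count", "exposure", "stratum")]
  }
  rownames(d) <- NULL
  attr(d, "lag") <- as.integer(lag)
  attr(d, "spline_df") <- as.integer(spline_df)
  attr(d, "n_dropped_missing") <- n_missing
  attr(d, "n_dropped_stratum_rows") <- n_stratum_rows
  attr(d, "n_dropped_strata") <- length(bad)
  attr(d, "knots") <- knots
  class(d) <- c("cc_dataset", "data.frame")
  d
}

model_matrix_cols <- function(data) {
  setdiff(names(data), c("date", "count", "stratum"))
}

#' Fit the conditional Poisson case-crossover model
#'
#' Maximises the conditional log-likelihood
#' \deqn{\ell(\theta) = \sum_s \Big[\sum_{t \in s} y_t \eta_t
#'   - Y_s \log \sum_{t \in s} e^{\eta_t}\Big],\qquad
#'   \eta_t = \beta x_t + \gamma' z_t,}
#' where the sum runs over year-month-weekday strata, \eqn{Y_s} is the
#' stratum count total, \eqn{x_t} the lagged exposure and \eqn{z_t} the
#' lagged weather spline basis.  Conditioning on the stratum totals
#' eliminates the stratum intercepts, so the fit is numerically
#' identical to a Poisson regression with one indicator per time
#' stratum but never forms those indicators.  Newton-Raphson with
#' step-halving; covariates are centred within stratum (which leaves
#' the likelihood unchanged) for numerical stability; standard errors
#' come from the inverse observed information.
#'
#' @param data a [build_cc_dataset()] result.
#' @param tol convergence tolerance on the relative change in the
#'   conditional log-likelihood (default 1e-8).
#' @param max_iter maximum Newton iterations (default 100).
#' @return object of class `cc_fit`: `beta` (slope per unit of the
#'   exposure's declared scale), `se`, `p_value` (two-sided Wald),
#'   `n_rows`, `n_strata`, `converged`, `iterations`,
#'   `log_likelihood`, plus the full coefficient vector and its
#'   covariance.
#' @export
fit_conditional_poisson <- function(data, tol = 1e-8, max_iter = 100L) {
  cols <- model_matrix_cols(data)
  if (!"exposure" %in% cols) stopf("data has no exposure column")
  X <- as.matrix(data[cols])
  storage.mode(X) <- "double"
  y <- as.numeric(data$count)
  s <- factor(data$stratum)
  si <- as.integer(s)
  n_strata <- nlevels(s)
  Y <- as.numeric(rowsum(y, si)[, 1])

  # centre covariates within stratum: invariant for the conditional
  # likelihood, but keeps exp() well scaled and the information matrix
  # well conditioned
  Xc <- X - apply(X, 2, function(col) ave(col, si))

  if (max(abs(Xc[, "exposure"])) < 1e-12)
    stopf("exposure is constant within every time stratum: slope not identified")
  keep <- colnames(Xc) == "exposure" |
    apply(Xc, 2, function(col) max(abs(col)) > 1e-10)
  dropped_cols <- colnames(Xc)[!keep]
  Xc <- Xc[, keep, drop = FALSE]
  p <- ncol(Xc)

  loglik <- function(eta) {
    m <- as.numeric(tapply(eta, si, max))
    denom <- as.numeric(rowsum(exp(eta - m[si]), si)[, 1])
    sum(y * eta) - sum(Y * (log(denom) + m))
  }
  theta <- rep(0, p)
  eta <- rep(0, nrow(Xc))
  ll <- loglik(eta)
  converged <- FALSE
  iter <- 0L
  H <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    m <- as.numeric(tapply(eta, si, max))
    ex <- exp(eta - m[si])
    denom <- as.numeric(rowsum(ex, si)[, 1])
    pr <- ex / denom[si]
    mu <- Y[si] * pr
    grad <- crossprod(Xc, y - mu)
    W <- rowsum(Xc * pr, si)
    H <- crossprod(Xc * mu, Xc) - crossprod(W * sqrt(Y))
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step))
      stopf("information matrix is singular: model not identified%s",
            if (length(dropped_cols))
              sprintf(" (degenerate columns: %s)",
                      paste(dropped_cols, collapse = ", ")) else "")
    ll_new <- loglik(eta + drop(Xc %*% step))
    halvings <- 0L
    while (!is.finite(ll_new) || ll_new < ll - 1e-12) {
      step <- step / 2
      halvings <- halvings + 1L
      if (halvings > 30L) break
      ll_new <- loglik(eta + drop(Xc %*% step))
    }
    theta <- theta + drop(step)
    eta <- drop(Xc %*% theta)
    done <- abs(ll_new - ll) < tol * (abs(ll) + tol)
    ll <- ll_new
    if (done) { converged <- TRUE; break }
  }
  # observed information at the optimum
  m <- as.numeric(tapply(eta, si, max))
  ex <- exp(eta - m[si])
  denom <- as.numeric(rowsum(ex, si)[, 1])
  pr <- ex / denom[si]
  mu <- Y[si] * pr
  W <- rowsum(Xc * pr, si)
  H <- crossprod(Xc * mu, Xc) - crossprod(W * sqrt(Y))
  vcov <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, p, p))
  names(theta) <- colnames(Xc)
  dimnames(vcov) <- list(colnames(Xc), colnames(Xc))
  beta <- theta[["exposure"]]
  se <- sqrt(vcov["exposure", "exposure"])
  out <- list(beta = beta, se = se,
              p_value = if (is.finite(se) && se > 0) wald_p(beta, se)
                        else NA_real_,
              n_rows = nrow(data), n_strata = n_strata,
              converged = converged, iterations = iter,
              log_likelihood = ll, coefficients = theta, vcov = vcov,
              dropped_columns = dropped_cols,
              lag = attr(data, "lag"),
              spline_df = attr(data, "spline_df"))
  class(out) <- "cc_fit"
  out
}

#' @export
print.cc_fit <- function(x, ...) {
  cat("Conditional Poisson case-crossover fit\n")
  cat(sprintf("  beta = %.6g  (se %.3g, p %.3g)\n", x$beta, x$se, x$p_value))
  cat(sprintf("  rows %d, strata %d, lag %s, %sconverged in %d iterations\n",
              x$n_rows, x$n_strata, format(x$lag),
              if (x$converged) "" else "NOT ", x$iterations))
  invisible(x)
}

#' Two-sided Wald p-value
#'
#' `p = 2 * (1 - Phi(|beta / se|))` under the standard normal
#' approximation to the Wald statistic.
#'
#' @param beta estimated slope.
#' @param se its standard error (> 0).
#' @return p-value in (0, 1].
#' @export
wald_p <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stopf("se must be > 0")
  2 * stats::pnorm(-abs(beta / se))
}

#' Relative risk for a concentration increment
#'
#' Converts a fitted slope into the relative risk of an event per
#' `increment` units of the exposure, `RR = exp(beta * increment)`,
#' with the 95\% Wald confidence interval
#' `exp((beta +/- 1.959964 * se) * increment)`.
#'
#' @param fit a converged [fit_conditional_poisson()] result (or any
#'   list with `beta`, `se`, `converged`).
#' @param increment concentration increment (> 0) in the exposure's
#'   declared units; a common choice is the interquartile range of the
#'   daily series (see [iqr_increment()]).
#' @return list with `rr`, `lower`, `upper` and `increment`.
#' @export
relative_risk <- function(fit, increment = 1) {
  if (!isTRUE(fit$converged)) stopf("relative risk requires a converged fit")
  if (!is_scalar_number(increment) || increment <= 0)
    stopf("increment must be > 0")
  z <- stats::qnorm(0.975)
  list(rr = exp(fit$beta * increment),
       lower = exp((fit$beta - z * fit$se) * increment),
       upper = exp((fit$beta + z * fit$se) * increment),
       increment = increment)
}

#' Interquartile-range increment of a daily series
#'
#' The default reporting increment for relative risks: the IQR of the
#' observed daily values.
#'
#' @param series an [exposure_series()] or `date`/`value` data frame.
#' @return single number, the IQR of the non-missing values.
#' @export
iqr_increment <- function(series) {
  stats::IQR(series$value, na.rm = TRUE)
}
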
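#' Default disease chapters and pollutants
#'
#' The 12 ICD-10 chapter code ranges analysed as outcome groups, and
#' the 8 exposures (six measured pollutants plus the two composite
#' indices) in alphabetical order.
#'
#' @return character vector.
#' @export
default_chapters <- function() {
  c("A00-B99", "F00-F99", "G00-G99", "H00-H59", "H60-H95", "I00-I99",
    "J00-J99", "K00-K93", "L00-L99", "M00-M99", "N00-N99", "S00-T98")
}

#' @rdname default_chapters
#' @export
default_pollutants <- function() {
  c("AQHI", "AQHIX", "CO", "NO2", "O3", "O3H8", "PM25", "SO2")
}

#' Analysis configuration
#'
#' Bundles everything needed to run the full case-crossover analysis:
#' the inputs (a [sim_config()] for synthetic mode, or file paths to
#' daily CSVs), the model grid (pollutants, chapters, strata, lags),
#' the spline dimension, the significance thresholds and the output
#' directory.  With the defaults the grid has 8 pollutants x 18
#' strata x 15 lags = 2160 models per disease chapter.
#'
#' @param sim a [sim_config()]; synthetic mode generates all inputs
#'   from it.
#' @param inputs alternatively, a list with `counts` (CSV with columns
#'   `date,chapter,sex,age,count`), `weather` (CSV with
#'   `date,temp,rh`) and `exposures` (named character vector of daily
#'   series CSV paths, one per pollutant).
#' @param pollutants exposures to model (default the 8 of
#'   [default_pollutants()]); `AQHI`/`AQHIX` are derived from NO2, O3,
#'   O3H8 and PM2.5 when not supplied directly.
#' @param chapters outcome groups (default the 12 ICD-10 ranges).
#' @param lags integer lags (default 0:14).
#' @param spline_df natural-spline dimension for each weather variable.
#' @param p_thresholds two strict significance thresholds, the main
#'   one first (default `c(0.05, 0.001)`).
#' @param rr_increment `"iqr"` (per-pollutant interquartile range) or
#'   a number of concentration units.
#' @param age_breaks passed to [enumerate_patient_strata()].
#' @param output_dir where [run_full_analysis()] writes its bundle;
#'   `NULL` keeps everything in memory.
#' @param seed integer seed for synthetic mode.
#' @return validated list of class `analysis_config`.
#' @export
analysis_config <- function(sim = NULL, inputs = NULL,
                            pollutants = default_pollutants(),
                            chapters = default_chapters(),
                            lags = 0:14, spline_df = 3L,
                            p_thresholds = c(0.05, 0.001),
                            rr_increment = "iqr",
                            age_breaks = c(10L, 60L),
                            output_dir = NULL, seed = 1L) {
  if (is.null(sim) && is.null(inputs))
    stopf("provide either a sim_config or input paths")
  if (!length(pollutants)) stopf("pollutant list is empty")
  if (!length(chapters)) stopf("chapter list is empty")
  if (any(lags < 0 | lags > 14)) stopf("lags must lie in 0..14")
  if (length(p_thresholds) < 1 || any(p_thresholds <= 0 | p_thresholds >= 1))
    stopf("p_thresholds must lie in (0, 1)")
  cfg <- list(sim = sim, inputs = inputs, pollutants = pollutants,
              chapters = chapters, lags = as.integer(lags),
              spline_df = as.integer(spline_df),
              p_thresholds = p_thresholds, rr_increment = rr_increment,
              age_breaks = age_breaks, output_dir = output_dir,
              seed = as.integer(seed))
  class(cfg) <- "analysis_config"
  cfg
}

#' Enumerate the model grid
#'
#' Lists every model cell (chapter, pollutant, stratum, lag) in
#' deterministic order: chapters outermost, then pollutants, strata
#' and lags.  With the default configuration this is 2160 cells per
#' chapter and 25,920 in total.
#'
#' @param config an [analysis_config()].
#' @return data frame with columns `chapter`, `pollutant`, `stratum`,
#'   `lag`, one row per model.
#' @export
enumerate_model_grid <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  strata <- enumerate_patient_strata(config$age_breaks)$label
  g <- expand.grid(lag = config$lags, stratum = strata,
                   pollutant = config$pollutants,
                   chapter = config$chapters,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[c("chapter", "pollutant", "stratum", "lag")]
}

## resolve all exposure series for the configured pollutants,
## deriving AQHI/AQHIX from their constituents when needed
resolve_exposures <- function(config, measured) {
  out <- measured
  need_idx <- intersect(c("AQHI", "AQHIX"), config$pollutants)
  for (nm in need_idx) {
    if (!is.null(out[[nm]])) next
    o3_name <- if (nm == "AQHI") "O3" else "O3H8"
    req <- c("NO2", o3_name, "PM25")
    if (!all(req %in% names(out)))
      stopf("%s requires series for %s", nm, paste(req, collapse = ", "))
    dates <- out$NO2$date
    idx <- function(s) s$value[match(dates, s$date)]
    out[[nm]] <- exposure_series(
      dates, compute_aqhi(idx(out$NO2), idx(out[[o3_name]]),
                          idx(out$PM25)), nm, "index")
  }
  missing_p <- setdiff(config$pollutants, names(out))
  if (length(missing_p))
    stopf("no exposure series for: %s", paste(missing_p, collapse = ", "))
  out[config$pollutants]
}

load_inputs <- function(config) {
  if (!is.null(config$sim)) {
    measured <- simulate_pollutants(config$sim)
    weather <- simulate_weather(config$sim)
    exposures <- resolve_exposures(config, measured)
    target <- exposures[[config$sim$effect$pollutant]] %||%
      measured[[config$sim$effect$pollutant]]
    counts <- lapply(seq_along(config$chapters), function(i) {
      cfg_i <- config$sim
      cfg_i$seed <- config$sim$seed + 1000L * i
      chapter_counts <- simulate_counts(cfg_i, target, weather)
      split_counts(chapter_counts, config$sim$sex_age_proportions,
                   seed = cfg_i$seed)
    })
    names(counts) <- config$chapters
    list(exposures = exposures, weather = weather, counts = counts)
  } else {
    inp <- config$inputs
    weather <- utils::read.csv(inp$weather, stringsAsFactors = FALSE)
    weather$date <- as_iso_date(weather$date, "weather date")
    measured <- lapply(names(inp$exposures), function(nm)
      read_daily_series(inp$exposures[[nm]], nm))
    names(measured) <- names(inp$exposures)
    exposures <- resolve_exposures(config, measured)
    long <- utils::read.csv(inp$counts, stringsAsFactors = FALSE)
    long$date <- as_iso_date(long$date, "counts date")
    counts <- split(long[c("date", "sex", "age", "count")], long$chapter)
    counts <- counts[intersect(config$chapters, names(counts))]
    if (!setequal(names(counts), config$chapters))
      stopf("counts file does not cover all configured chapters")
    list(exposures = exposures, weather = weather, counts = counts)
  }
}

#' Run the full case-crossover analysis
#'
#' Executes every model in the grid: for each (chapter, pollutant,
#' stratum, lag) cell the stratum's daily counts are joined with the
#' lagged exposure and weather, the conditional Poisson model is
#' fitted, and the slope, standard error and Wald p-value are recorded
#' in a flat results table.  Binary association matrices are then
#' built per chapter and pollutant at each configured threshold,
#' summed across chapters per pollutant, and condensed into the
#' counting summaries and the persistence report.  Cells whose data
#' are insufficient (empty strata, non-identified exposure) are logged
#' as skips and contribute 0 to the matrices.
#'
#' @param config an [analysis_config()].
#' @param progress print a line per chapter-pollutant block.
#' @return list of class `cc_analysis`: `results` (flat data frame),
#'   `binary` (nested list `[[threshold]][[pollutant]][[chapter]]`),
#'   `summed` (list `[[threshold]][[pollutant]]`), `summary` (counting
#'   summaries at the main threshold), `persistence` (per-chapter data
#'   frame), `diagnostics` and the echoed `config`.  When
#'   `config$output_dir` is set the bundle is also written to disk
#'   (results CSV, matrix CSVs, heatmaps, summary and persistence
#'   CSVs, run log JSON).
#' @export
run_full_analysis <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  grid <- enumerate_model_grid(config)
  strata_def <- enumerate_patient_strata(config$age_breaks)
  inputs <- load_inputs(config)

  rows <- vector("list", nrow(grid))
  skip_log <- character()
  cache <- new.env(parent = emptyenv())
  stratum_series <- function(chapter, label) {
    key <- paste(chapter, label, sep = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    st <- strata_def[strata_def$label == label, , drop = FALSE]
    cache[[key]] <- stratum_counts(inputs$counts[[chapter]], st)
    cache[[key]]
  }

  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (progress && g$lag == config$lags[1] &&
        g$stratum == strata_def$label[1])
      message(sprintf("fitting %s / %s", g$chapter, g$pollutant))
    row <- data.frame(chapter = g$chapter, stratum = g$stratum,
                      pollutant = g$pollutant, lag = g$lag,
                      beta = NA_real_, se = NA_real_, p = NA_real_,
                      n_rows = NA_integer_, n_strata = NA_integer_,
                      converged = FALSE, note = "")
    fit <- tryCatch({
      cs <- stratum_series(g$chapter, g$stratum)
      ds <- build_cc_dataset(cs, inputs$exposures[[g$pollutant]],
                             inputs$weather, g$lag, config$spline_df)
      fit_conditional_poisson(ds)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      row$note <- conditionMessage(fit)
      skip_log <- c(skip_log, sprintf("%s | %s | %s | lag %d: %s",
                                      g$chapter, g$pollutant, g$stratum,
                                      g$lag, row$note))
    } else {
      row$beta <- fit$beta; row$se <- fit$se; row$p <- fit$p_value
      row$n_rows <- fit$n_rows; row$n_strata <- fit$n_strata
      row$converged <- fit$converged
      if (!fit$converged)
        skip_log <- c(skip_log, sprintf(
          "%s | %s | %s | lag %d: did not converge", g$chapter,
          g$pollutant, g$stratum, g$lag))
    }
    rows[[i]] <- row
  }
  results <- do.call(rbind, rows)

  binary <- list(); summed <- list()
  for (thr in config$p_thresholds) {
    tkey <- format(thr)
    binary[[tkey]] <- lapply(config$pollutants, function(p) {
      ms <- lapply(config$chapters, function(ch) {
        r <- results[results$pollutant == p & results$chapter == ch, ]
        build_binary_matrix(r[c("stratum", "lag", "beta", "p",
                                "converged")],
                            strata = strata_def$label,
                            lags = config$lags, p_threshold = thr,
                            pollutant = p, chapter = ch)
      })
      names(ms) <- config$chapters
      ms
    })
    names(binary[[tkey]]) <- config$pollutants
    summed[[tkey]] <- lapply(binary[[tkey]], sum_matrices,
                             n_expected = length(config$chapters))
  }
  main_key <- format(config$p_thresholds[1])
  summary <- count_summaries(summed[[main_key]],
                             n_chapters = length(config$chapters))

  persistence <- NULL
  if (length(config$p_thresholds) >= 2) {
    k2 <- format(config$p_thresholds[2])
    persistence <- do.call(rbind, lapply(config$chapters, function(ch) {
      a <- sum(vapply(binary[[main_key]], function(pp)
        sum(pp[[ch]]), numeric(1)))
      b <- sum(vapply(binary[[k2]], function(pp)
        sum(pp[[ch]]), numeric(1)))
      data.frame(chapter = ch, n_main = a, n_strict = b,
                 persistence_pct = persistence_ratio(a, b))
    }))
  }
  diagnostics <- list(n_models = nrow(grid),
                      n_fitted = sum(!is.na(results$beta)),
                      n_skipped = sum(is.na(results$beta)),
                      n_nonconverged = sum(!results$converged &
                                             !is.na(results$beta)),
                      skips = skip_log)
  out <- list(results = results, binary = binary, summed = summed,
              summary = summary, persistence = persistence,
              diagnostics = diagnostics, config = config)
  class(out) <- "cc_analysis"
  if (!is.null(config$output_dir)) write_analysis_bundle(out)
  out
}

write_analysis_bundle <- function(analysis) {
  config <- analysis$config
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(analysis$results, file.path(dir, "model_results.csv"),
                   row.names = FALSE)
  mdir <- file.path(dir, "matrices")
  dir.create(mdir, showWarnings = FALSE)
  main_key <- format(config$p_thresholds[1])
  for (p in config$pollutants) {
    for (ch in names(analysis$binary[[main_key]][[p]]))
      write_matrix_csv(analysis$binary[[main_key]][[p]][[ch]],
                       file.path(mdir, sprintf("binary_%s_%s.csv", p, ch)))
    export_heatmap(analysis$summed[[main_key]][[p]],
                   file.path(mdir, paste0("summed_", p)),
                   max_value = length(config$chapters))
  }
  utils::write.csv(
    cbind(stratum = rownames(analysis$summary$table),
          analysis$summary$table),
    file.path(dir, "summary_table.csv"), row.names = FALSE)
  if (!is.null(analysis$persistence))
    utils::write.csv(analysis$persistence,
                     file.path(dir, "persistence.csv"), row.names = FALSE)
  log <- list(seed = config$seed, pollutants = config$pollutants,
              chapters = config$chapters, lags = config$lags,
              spline_df = config$spline_df,
              p_thresholds = config$p_thresholds,
              diagnostics = analysis$diagnostics[
                c("n_models", "n_fitted", "n_skipped", "n_nonconverged")],
              skips = analysis$diagnostics$skips)
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.cc_analysis <- function(x, ...) {
  cat("Case-crossover analysis\n")
  cat(sprintf("  %d models (%d chapters x %d pollutants x %d strata x %d lags)\n",
              x$diagnostics$n_models, length(x$config$chapters),
              length(x$config$pollutants), 18L, length(x$config$lags)))
  cat(sprintf("  fitted %d, skipped %d, non-converged %d\n",
              x$diagnostics$n_fitted, x$diagnostics$n_skipped,
              x$diagnostics$n_nonconverged))
  cat("  positive associations per pollutant:\n")
  print(x$summary$totals)
  invisible(x)
}
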
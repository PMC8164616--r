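#' Binary association matrix for one disease chapter and pollutant
#'
#' Collapses a grid of model results into the qualitative 18 x 15
#' marker matrix: rows are the patient strata (fixed order), columns
#' the lags 0-14, and a cell is 1 exactly when the fitted slope is
#' positive and its two-sided p-value falls strictly below the
#' threshold.  Negative, non-significant, missing and non-converged
#' results all yield 0; non-converged and missing cells are tallied in
#' the attributes so fit failures are never silently absorbed.
#'
#' @param results data frame with one row per (stratum, lag):
#'   columns `stratum` (label matching `strata`), `lag`, `beta`, `p`
#'   and optionally `converged` (missing treated as `TRUE`).
#' @param strata stratum labels in row order (default the 18 labels of
#'   [enumerate_patient_strata()]).
#' @param lags lag columns (default 0:14).
#' @param p_threshold strict significance threshold (default 0.05; use
#'   0.001 for the persistence sensitivity analysis).
#' @param pollutant,chapter identifiers attached to the result.
#' @return integer matrix of class `association_matrix` with cells in
#'   \{0, 1\}, `dimnames` the stratum labels and `lag0..lag14`, and
#'   attributes `pollutant`, `chapter`, `p_threshold`,
#'   `n_nonconverged`, `n_missing`.
#' @export
build_binary_matrix <- function(results,
                                strata = enumerate_patient_strata()$label,
                                lags = 0:14, p_threshold = 0.05,
                                pollutant = NULL, chapter = NULL) {
  need <- c("stratum", "lag", "beta", "p")
  if (!is.data.frame(results) || !all(need %in% names(results)))
    stopf("results needs columns stratum, lag, beta, p")
  extra <- setdiff(unique(results$stratum), strata)
  if (length(extra))
    stopf("unknown strata in results: %s", paste(extra, collapse = ", "))
  if (any(!results$lag %in% lags))
    stopf("results contain lags outside the configured range")
  if (anyDuplicated(results[c("stratum", "lag")]))
    stopf("more than one result for the same (stratum, lag) cell")
  conv <- if ("converged" %in% names(results)) results$converged else TRUE
  conv <- ifelse(is.na(conv), FALSE, conv)

  m <- matrix(0L, nrow = length(strata), ncol = length(lags),
              dimnames = list(strata, paste0("lag", lags)))
  ri <- match(results$stratum, strata)
  ci <- match(results$lag, lags)
  hit <- conv & !is.na(results$beta) & !is.na(results$p) &
    results$beta > 0 & results$p < p_threshold
  m[cbind(ri[hit], ci[hit])] <- 1L
  attr(m, "pollutant") <- pollutant
  attr(m, "chapter") <- chapter
  attr(m, "p_threshold") <- p_threshold
  attr(m, "n_nonconverged") <- sum(!conv)
  attr(m, "n_missing") <- length(strata) * length(lags) - nrow(results)
  class(m) <- c("association_matrix", class(m))
  m
}

#' Sum binary matrices across disease chapters
#'
#' Cell-wise sum of the chapter-level binary matrices for one
#' pollutant; with the 12 chapters the cells range from 0 to 12, each
#' cell counting the disease chapters showing a positive significant
#' association at that (stratum, lag).
#'
#' @param matrices list of [build_binary_matrix()] results for the
#'   same pollutant, one per chapter (default expectation: 12).
#' @param n_expected required number of matrices (default 12); set to
#'   `NA` to skip the check.
#' @return summed `association_matrix` (chapter attribute absent).
#' @export
sum_matrices <- function(matrices, n_expected = 12L) {
  if (!length(matrices)) stopf("no matrices to sum")
  if (!is.na(n_expected) && length(matrices) != n_expected)
    stopf("expected %d matrices, got %d", n_expected, length(matrices))
  dims <- lapply(matrices, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stopf("matrices differ in shape")
  pols <- unique(unlist(lapply(matrices, attr, "pollutant")))
  if (length(pols) > 1L)
    stopf("matrices mix pollutants: %s", paste(pols, collapse = ", "))
  out <- Reduce(`+`, lapply(matrices, function(m) {
    m2 <- unclass(m)
    attributes(m2)[setdiff(names(attributes(m2)),
                           c("dim", "dimnames"))] <- NULL
    m2
  }))
  attr(out, "pollutant") <- if (length(pols)) pols else NULL
  attr(out, "p_threshold") <- attr(matrices[[1]], "p_threshold")
  attr(out, "n_chapters") <- length(matrices)
  class(out) <- c("association_matrix", class(out))
  out
}

#' Counting summaries over summed matrices
#'
#' Reproduces the tabular summaries used to report the matrices: the
#' per-pollutant total number of positive associations, the
#' per-stratum row totals over the 15 lags, the per-pollutant maximum
#' row total, and the percentage of positive results among all tested
#' models.  Because the published percentage row is ambiguous about
#' its denominator, two percentages are reported: `pct_of_cells`
#' (total / (strata x lags x chapters) x 100, the share of all fitted
#' models that were positive significant) and `pct_of_max` (total
#' relative to a saturated matrix of row maxima); both are returned so
#' the choice is explicit.
#'
#' @param summed named list of summed matrices (one per pollutant), as
#'   from [sum_matrices()].
#' @param n_chapters chapters each matrix was summed over (default
#'   taken from the matrices, falling back to 12).
#' @return list with `totals` (named vector), `row_totals` (strata x
#'   pollutants matrix), `maxima` (named vector of the largest row
#'   total per pollutant), `pct_of_cells` and a `table` data frame
#'   with one row per stratum plus `Maximum` and `% of all tested`.
#' @export
count_summaries <- function(summed, n_chapters = NULL) {
  if (is.null(names(summed)))
    names(summed) <- vapply(summed, function(m)
      attr(m, "pollutant") %||% "?", "")
  totals <- vapply(summed, sum, numeric(1))
  row_totals <- vapply(summed, rowSums, numeric(nrow(summed[[1]])))
  maxima <- apply(row_totals, 2, max)
  nch <- n_chapters %||% (attr(summed[[1]], "n_chapters") %||% 12L)
  n_tested <- nrow(summed[[1]]) * ncol(summed[[1]]) * nch
  pct <- totals / n_tested * 100
  tab <- as.data.frame(rbind(row_totals,
                             `Maximum` = maxima,
                             `% of all tested` = round(pct, 1)),
                       check.names = FALSE)
  list(totals = totals, row_totals = row_totals, maxima = maxima,
       pct_of_cells = pct, n_tested = n_tested, table = tab)
}

#' Persistence of associations under a stricter threshold
#'
#' The percentage of associations significant at the looser threshold
#' that remain significant at the stricter one, `100 * b / a`.
#'
#' @param count_p05 number of positive significant associations at the
#'   looser threshold (a, > 0).
#' @param count_p001 number still significant at the stricter
#'   threshold (b, with 0 <= b <= a).
#' @return percentage; `NA` when `a` is 0 (undefined).
#' @export
persistence_ratio <- function(count_p05, count_p001) {
  if (is.na(count_p05) || count_p05 == 0) return(NA_real_)
  if (count_p001 < 0 || count_p001 > count_p05)
    stopf("need 0 <= count_p001 <= count_p05")
  100 * count_p001 / count_p05
}

#' Write an association matrix to CSV
#'
#' Rows are the strata in fixed order, columns the lags 0-14; the CSV
#' round-trips the cell values exactly.
#'
#' @param matrix an `association_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(matrix, path) {
  df <- data.frame(stratum = rownames(matrix), unclass(matrix)[,],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  class(m) <- c("association_matrix", class(m))
  m
}

#' Render an association matrix heatmap
#'
#' Writes the matrix both as CSV and as a PNG heatmap with a linear
#' green-to-red ramp over the value range and the numeric value
#' printed in each cell; the numbers, not the colours, are the
#' contract.
#'
#' @param matrix an `association_matrix`.
#' @param path output path without extension; `<path>.csv` and
#'   `<path>.png` are written.
#' @param max_value top of the colour scale (default 12 for summed
#'   matrices; use 1 for binary ones).
#' @return invisible character vector of the two paths written.
#' @export
export_heatmap <- function(matrix, path, max_value = 12) {
  csv <- paste0(path, ".csv")
  png <- paste0(path, ".png")
  write_matrix_csv(matrix, csv)
  nr <- nrow(matrix); nc <- ncol(matrix)
  ramp <- grDevices::colorRampPalette(c("darkgreen", "yellow", "red"))(64)
  grDevices::png(png, width = 160 + 40 * nc, height = 80 + 28 * nr)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(3, 9, 3, 1))
  z <- t(unclass(matrix)[nr:1, , drop = FALSE])
  graphics::image(x = seq_len(nc), y = seq_len(nr), z = z,
                  zlim = c(0, max_value), col = ramp, axes = FALSE,
                  xlab = "", ylab = "",
                  main = attr(matrix, "pollutant") %||% "")
  graphics::axis(1, at = seq_len(nc), labels = colnames(matrix),
                 las = 2, cex.axis = 0.8)
  graphics::axis(2, at = seq_len(nr), labels = rev(rownames(matrix)),
                 las = 1, cex.axis = 0.8)
  for (i in seq_len(nr))
    for (j in seq_len(nc))
      graphics::text(j, nr + 1 - i, matrix[i, j], cex = 0.8)
  invisible(c(csv, png))
}
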
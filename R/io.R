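#' Read a unit-level dataset from CSV
#'
#' The file must carry a header naming the two binary response columns
#' and the predictor columns; responses must be coded 0/1 and predictors
#' numeric, with no missing cells. Extra columns are ignored with a
#' warning. Row order is preserved.
#'
#' @param path Path to a CSV file (RFC-4180, UTF-8, '.' decimal).
#' @param response_cols Character vector of the two response column
#'   names (first = y1, second = y2).
#' @param predictor_cols Character vector of predictor column names;
#'   default: every other column.
#' @return List with \code{responses} (a \code{"bpblr_response"}) and
#'   \code{predictors} (data frame).
#' @export
read_dataset <- function(path, response_cols,
                         predictor_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (length(response_cols) != 2L)
    stop("exactly two response columns are required")
  missing_cols <- setdiff(response_cols, names(df))
  if (length(missing_cols) > 0L)
    stop(sprintf("unknown response column '%s'; available: %s",
                 missing_cols[1L], paste(names(df), collapse = ", ")))
  if (is.null(predictor_cols))
    predictor_cols <- setdiff(names(df), response_cols)
  missing_cols <- setdiff(predictor_cols, names(df))
  if (length(missing_cols) > 0L)
    stop(sprintf("unknown predictor column '%s'; available: %s",
                 missing_cols[1L], paste(names(df), collapse = ", ")))
  extra <- setdiff(names(df), c(response_cols, predictor_cols))
  if (length(extra) > 0L)
    warning("ignoring unused columns: ", paste(extra, collapse = ", "))
  pred <- df[predictor_cols]
  bad <- which(!vapply(pred, is.numeric, logical(1)))
  if (length(bad) > 0L)
    stop("non-numeric predictor column: ", predictor_cols[bad[1L]])
  na_cell <- which(is.na(as.matrix(pred)), arr.ind = TRUE)
  if (nrow(na_cell) > 0L)
    stop(sprintf("missing value at row %d, column '%s'",
                 na_cell[1L, 1L], predictor_cols[na_cell[1L, 2L]]))
  responses <- response_data(df[[response_cols[1L]]], df[[response_cols[2L]]])
  list(responses = responses, predictors = pred)
}

#' Write a synthetic dataset (and its truth) to disk
#'
#' @param sim Output of \code{\link{simulate_bpblr}}.
#' @param path CSV path for the unit-level data (columns \code{y1},
#'   \code{y2}, then the predictors).
#' @param truth_path Optional JSON path for the generating parameters,
#'   degrees, and seed.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(sim, path, truth_path = NULL) {
  df <- data.frame(y1 = sim$responses$y1, y2 = sim$responses$y2,
                   sim$predictors, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path))
    jsonlite::write_json(list(truth = as.list(sim$truth),
                              degrees = sim$degrees, seed = sim$seed),
                         truth_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# serialize a fit + tests to a plain-text or JSON report
fit_report <- function(fit, alpha = 0.05, seed = NULL, options = list()) {
  wald <- wald_partial_tests(fit, alpha)
  tst <- if (length(fit$degrees) > 0L)
    mlrt_simultaneous(fit, fit_null(fit$data), alpha)
  list(version = as.character(utils::packageVersion("bpblr")),
       seed = seed, options = options,
       degrees = fit$degrees, n = fit$n, converged = fit$converged,
       n_iter = fit$n_iter, loglik = fit$loglik, deviance = fit$deviance,
       estimates = wald,
       mlrt = if (!is.null(tst))
         list(statistic = tst$statistic, df = tst$df,
              p_value = tst$p_value, critical_value = tst$critical_value,
              alpha = alpha, reject = tst$reject))
}

write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    w <- report$estimates
    writeLines(c(
      sprintf("bpblr %s  (seed: %s)", report$version,
              if (is.null(report$seed)) "none" else report$seed),
      sprintf("degrees: %s  n: %d  converged: %s  iterations: %d",
              paste(report$degrees, collapse = ","), report$n,
              report$converged, report$n_iter),
      sprintf("logLik: %.6f  deviance: %.6f", report$loglik, report$deviance),
      "", "parameter estimates:",
      utils::capture.output(print(w, row.names = FALSE)),
      "",
      if (!is.null(report$mlrt))
        sprintf("simultaneous G2 = %.6f, df = %d, p = %.6g (critical %.4f at alpha = %g) -> %s H0",
                report$mlrt$statistic, report$mlrt$df, report$mlrt$p_value,
                report$mlrt$critical_value, report$mlrt$alpha,
                if (report$mlrt$reject) "reject" else "do not reject")
      else character(0)), con)
  }
  invisible(path)
}
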
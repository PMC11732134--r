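#' Univariable significance screen
#'
#' For each predictor \eqn{j} and each degree \eqn{d = 1, \ldots,}
#' \code{max_degree}, fits a single-predictor model of degree \eqn{d}
#' (the design contains all powers up to \eqn{d}) and runs the
#' simultaneous likelihood ratio test against the intercept-only null
#' (\eqn{df = 3d}). A predictor passes the screen when it is
#' significant at any tested degree.
#'
#' @param data A \code{"bpblr_response"}.
#' @param predictors Data frame or matrix of raw predictors.
#' @param max_degree Highest polynomial degree to test (default 2).
#' @param alpha Significance level (default 0.05).
#' @param standardize Passed to \code{\link{build_design}}.
#' @param ... Passed to \code{\link{fit_bpblr}}.
#' @return List with \code{table} (one row per predictor x degree:
#'   \code{predictor}, \code{degree}, \code{g2}, \code{df},
#'   \code{p_value}, \code{significant}, \code{converged}) and
#'   \code{passed} (predictor names significant at some degree).
#'   Non-convergent cells are recorded with \code{NA} statistics and do
#'   not by themselves exclude a predictor.
#' @export
univariable_screen <- function(data, predictors, max_degree = 2L,
                               alpha = 0.05, standardize = FALSE, ...) {
  if (max_degree < 1L) stop("'max_degree' must be >= 1")
  predictors <- as.data.frame(predictors)
  null <- fit_null(data, ...)
  rows <- list()
  for (j in seq_along(predictors)) {
    nm <- names(predictors)[j]
    for (d in seq_len(max_degree)) {
      des <- build_design(predictors[j], degrees = d,
                          standardize = standardize)
      fit <- fit_bpblr(data, des, ...)
      if (fit$converged) {
        tst <- mlrt_simultaneous(fit, null, alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          predictor = nm, degree = d, g2 = tst$statistic, df = tst$df,
          p_value = tst$p_value, significant = tst$reject, converged = TRUE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          predictor = nm, degree = d, g2 = NA_real_, df = 3L * d,
          p_value = NA_real_, significant = NA, converged = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  passed <- unique(tab$predictor[!is.na(tab$significant) & tab$significant])
  list(table = tab, passed = passed)
}

#' Exhaustive degree-grid search by minimum deviance
#'
#' Fits every combination of per-predictor polynomial degrees in
#' \eqn{\{1, \ldots, \mathrm{max\_degree}\}^k} and returns all deviances
#' with the argmin. Ties in minimum deviance are broken by smallest
#' total degree \eqn{\sum_j r_j}, then lexicographically. Each grid fit
#' warm-starts from the all-degree-1 fit's parameters padded with zeros
#' in the new power positions.
#'
#' @inheritParams univariable_screen
#' @param max_degree Highest degree per predictor (default 2). The grid
#'   has \code{max_degree^k} rows; a warning is issued above 4096.
#' @return Object of class \code{"bpblr_grid"}: list with \code{rows}
#'   (data frame in lexicographic degree order: one degree column per
#'   predictor, \code{deviance}, \code{converged}), \code{best} (degree
#'   vector), \code{best_deviance}, and \code{best_fit}.
#' @export
degree_grid_search <- function(data, predictors, max_degree = 2L,
                               standardize = FALSE, ...) {
  predictors <- as.data.frame(predictors)
  k <- ncol(predictors)
  if (k < 1L) stop("need at least one predictor")
  if (max_degree < 1L) stop("'max_degree' must be >= 1")
  n_comb <- max_degree^k
  if (n_comb > 4096) warning(sprintf("degree grid has %d combinations", n_comb))
  grid <- as.matrix(expand.grid(rev(replicate(k, seq_len(max_degree),
                                              simplify = FALSE)))[, k:1, drop = FALSE])
  colnames(grid) <- names(predictors)
  base_des <- build_design(predictors, degrees = rep(1L, k),
                           standardize = standardize)
  base_fit <- fit_bpblr(data, base_des, ...)
  fits <- vector("list", nrow(grid))
  dev <- conv <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    degs <- grid[i, ]
    des <- build_design(predictors, degrees = degs, standardize = standardize)
    start <- if (base_fit$converged)
      pad_theta(base_fit$theta, rep(1L, k), degs) else NULL
    fit <- fit_bpblr(data, des, start = start, ...)
    fits[[i]] <- fit
    dev[i] <- fit$deviance
    conv[i] <- fit$converged
  }
  if (!any(conv == 1)) stop("no grid fit converged")
  rows <- data.frame(grid, deviance = dev, converged = as.logical(conv))
  # argmin over converged rows; ties -> smallest total degree, then lexicographic
  cand <- which(rows$converged)
  cand_dev <- rows$deviance[cand]
  best_set <- cand[cand_dev <= min(cand_dev) + 0]
  if (length(best_set) > 1L) {
    tot <- rowSums(grid[best_set, , drop = FALSE])
    best_set <- best_set[order(tot, best_set)]
  }
  best_i <- best_set[1L]
  structure(list(rows = rows, best = grid[best_i, ],
                 best_deviance = rows$deviance[best_i],
                 best_fit = fits[[best_i]]),
            class = "bpblr_grid")
}

# embed a fitted theta for `from` degrees into the layout of `to` degrees
# (new power positions start at zero); both degree vectors share k
pad_theta <- function(theta, from, to) {
  m_from <- sum(from); m_to <- sum(to)
  th <- split_theta(theta, m_from)
  idx <- function(degs) {
    # map (predictor, power) -> block position for a degree vector
    off <- c(0L, cumsum(degs))
    lapply(seq_along(degs), function(j) off[j] + seq_len(degs[j]))
  }
  fi <- idx(from); ti <- idx(to)
  embed <- function(block) {
    out <- numeric(m_to)
    for (j in seq_along(from)) {
      keep <- seq_len(min(from[j], to[j]))
      out[ti[[j]][keep]] <- block[fi[[j]][keep]]
    }
    out
  }
  c(th$a1, embed(th$b1), th$a2, embed(th$b2), th$a3, embed(th$g))
}

#' @export
print.bpblr_grid <- function(x, digits = 4, ...) {
  cat(sprintf("Degree grid search: %d combinations\n", nrow(x$rows)))
  print(transform(x$rows, deviance = round(deviance, digits)),
        row.names = FALSE)
  cat("best degrees:", paste(x$best, collapse = ","),
      sprintf(" (deviance %.*f)", digits, x$best_deviance), "\n")
  invisible(x)
}
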
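#' Simultaneous maximum likelihood ratio test
#'
#' Tests whether any slope in any of the three links is nonzero:
#' \eqn{G^2 = 2(\ln L_{\mathrm{full}} - \ln L_{\mathrm{null}})}, equal
#' to the difference of deviances, referred to a chi-square with
#' \eqn{v = 3\sum_j r_j} degrees of freedom (the full model has
#' \eqn{3 + 3\sum r_j} parameters, the intercept-only null has 3).
#' The statistic is also recomputed in its direct cell-wise log-ratio
#' form as a cross-check; the two must agree to \code{1e-8}.
#'
#' @param full Full-model \code{"bpblr_fit"}.
#' @param null Null \code{"bpblr_fit"} on the same data
#'   (\code{\link{fit_null}}).
#' @param alpha Significance level (default 0.05).
#' @return Object of class \code{"bpblr_test"}: list with
#'   \code{statistic}, \code{df}, \code{p_value}, \code{critical_value},
#'   \code{reject}, \code{alpha}, \code{method}.
#' @export
mlrt_simultaneous <- function(full, null, alpha = 0.05) {
  if (full$n != null$n) stop("fits are not on the same data")
  g2 <- 2 * (full$loglik - null$loglik)
  if (g2 < -1e-8)
    stop(sprintf("negative likelihood-ratio statistic (%.3g): optimizer failure", g2))
  g2 <- max(g2, 0)
  # direct cell-wise form: sum of observed-cell log probability ratios
  lr_direct <- 2 * (sum(full$data$Y * log(pmax(
                      model_probabilities(full$theta, full$design)$cells, .EPS_P))) -
                    sum(null$data$Y * log(pmax(
                      model_probabilities(null$theta, null_design(null$n))$cells, .EPS_P))))
  if (abs(lr_direct - g2) > 1e-8 * max(1, abs(g2)))
    stop("internal error: the two likelihood-ratio forms disagree")
  df <- 3L * sum(full$degrees)
  make_test(g2, df, alpha, "Simultaneous likelihood ratio (G2)")
}

make_test <- function(statistic, df, alpha, method) {
  crit <- chi_square_critical(alpha, df)
  structure(list(statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 critical_value = crit, reject = statistic > crit,
                 alpha = alpha, method = method),
            class = "bpblr_test")
}

#' @export
print.bpblr_test <- function(x, digits = 4, ...) {
  cat(sprintf("%s: statistic = %.*f, df = %d, p = %.4g\n",
              x$method, digits, x$statistic, x$df, x$p_value))
  cat(sprintf("  critical value at alpha = %g: %.*f -> %s H0\n", x$alpha,
              digits, x$critical_value,
              if (x$reject) "reject" else "do not reject"))
  invisible(x)
}

#' Upper-tail chi-square critical value
#'
#' @param alpha Significance level in (0,1).
#' @param df Degrees of freedom (>= 1).
#' @return The upper-\code{alpha} quantile of \eqn{\chi^2_{df}}, e.g.
#'   28.8693 for \code{alpha = 0.05, df = 18}.
#' @export
chi_square_critical <- function(alpha, df) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (df < 1) stop("'df' must be >= 1")
  stats::qchisq(alpha, df, lower.tail = FALSE)
}

#' Partial Wald tests for every parameter
#'
#' Standard errors are square roots of the diagonal of the inverse BHHH
#' information; \eqn{z = \hat\theta / SE} with two-sided normal
#' p-values. An approximation: the outer-product information is exact
#' only in large samples.
#'
#' @param fit A converged \code{"bpblr_fit"}.
#' @param alpha Significance level for the \code{significant} flag.
#' @return Data frame with one row per parameter: \code{parameter},
#'   \code{estimate}, \code{se}, \code{z}, \code{p_value},
#'   \code{significant}, \code{flagged} (non-positive variance).
#' @export
wald_partial_tests <- function(fit, alpha = 0.05) {
  v <- diag(fit$covariance)
  flagged <- !is.finite(v) | v <= 0
  se <- rep(NA_real_, length(v))
  se[!flagged] <- sqrt(v[!flagged])
  z <- fit$theta / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(parameter = names(fit$theta), estimate = unname(fit$theta),
             se = unname(se), z = unname(z), p_value = unname(p),
             significant = unname(!flagged & p < alpha),
             flagged = unname(flagged), row.names = NULL)
}

#' @export
summary.bpblr_fit <- function(object, alpha = 0.05, ...) {
  out <- list(fit = object, wald = wald_partial_tests(object, alpha),
              mlrt = if (length(object$degrees) > 0L)
                mlrt_simultaneous(object, fit_null(object$data), alpha))
  class(out) <- "summary.bpblr_fit"
  out
}

#' @export
print.summary.bpblr_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  w <- x$wald
  w$estimate <- signif(w$estimate, digits)
  w$se <- signif(w$se, digits)
  w$z <- signif(w$z, digits)
  w$p_value <- signif(w$p_value, digits)
  print(w[, c("parameter", "estimate", "se", "z", "p_value", "significant")],
        row.names = FALSE)
  if (!is.null(x$mlrt)) print(x$mlrt, digits = digits)
  invisible(x)
}

#' Pearson and likelihood-ratio independence tests for a 2x2 table
#'
#' Against the independence expectation \eqn{E_{gh} = n_{g.}n_{.h}/n}:
#' Pearson \eqn{X^2 = \sum (O-E)^2/E} and
#' \eqn{G^2 = 2\sum O \ln(O/E)} (zero cells contribute 0), both on 1
#' degree of freedom.
#'
#' @param counts 2x2 matrix (or length-4 vector, row-major
#'   \code{(n00, n01, n10, n11)}) of nonnegative integer counts.
#' @param alpha Significance level.
#' @return List with elements \code{pearson} and \code{lr}, each a
#'   \code{"bpblr_test"}.
#' @examples
#' independence_tests(c(73, 5, 7, 34))  # Pearson 71.414, G2 75.927
#' @export
independence_tests <- function(counts, alpha = 0.05) {
  O <- if (is.matrix(counts)) counts else matrix(counts, 2, 2, byrow = TRUE)
  if (!all(dim(O) == c(2L, 2L))) stop("'counts' must be a 2x2 table")
  if (any(O < 0) || any(O != round(O))) stop("counts must be nonnegative integers")
  if (sum(O) < 1) stop("empty table")
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop("a zero row or column margin makes the independence test undefined")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  x2 <- sum((O - E)^2 / E)
  g2 <- 2 * sum(ifelse(O > 0, O * log(O / E), 0))
  list(pearson = make_test(x2, 1L, alpha, "Pearson chi-square"),
       lr = make_test(g2, 1L, alpha, "Likelihood-ratio chi-square"))
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1/(1 - R^2_j)} from the least-squares regression of raw
#' predictor \eqn{j} on the remaining raw predictors (degree-1, matching
#' the usual multicollinearity screen). Values at or above 10 are
#' flagged; exact collinearity yields \code{Inf}.
#'
#' @param x Data frame or matrix of raw predictors, \eqn{n > k \ge 2}.
#' @return Data frame with \code{predictor}, \code{vif}, \code{flagged}.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x)
  if (k < 2L) stop("VIF needs at least two predictors")
  if (nrow(x) <= k) stop("VIF needs more units than predictors")
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("x", seq_len(k))
  out <- vapply(seq_len(k), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = nms, vif = out, flagged = out >= 10,
             row.names = NULL)
}
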
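#' Bundle a pair of binary responses
#'
#' Validates the two binary response vectors and derives the one-hot
#' cell indicators \eqn{y_{gh,i} = 1\{y_{1i} = g, y_{2i} = h\}} used by
#' the multinomial likelihood (each unit is a single multinomial trial
#' over the four cells of the 2x2 table).
#'
#' @param y1,y2 Vectors coded 0/1, one element per unit.
#' @return Object of class \code{"bpblr_response"}: list with \code{y1},
#'   \code{y2}, the \eqn{n \times 4} indicator matrix \code{Y} (columns
#'   \code{p00}, \code{p01}, \code{p10}, \code{p11}, matching
#'   \code{\link{joint_cells}}), and \code{n}.
#' @export
response_data <- function(y1, y2) {
  y1 <- as.numeric(y1); y2 <- as.numeric(y2)
  if (length(y1) != length(y2)) stop("'y1' and 'y2' must have equal length")
  bad <- which(!(y1 %in% c(0, 1)) | !(y2 %in% c(0, 1)))
  if (length(bad) > 0L)
    stop(sprintf("non-binary response value in row %d", bad[1L]))
  Y <- cbind(p00 = (1 - y1) * (1 - y2), p01 = (1 - y1) * y2,
             p10 = y1 * (1 - y2),       p11 = y1 * y2)
  structure(list(y1 = y1, y2 = y2, Y = Y, n = length(y1)),
            class = "bpblr_response")
}

#' Multinomial log-likelihood of the bivariate logit model
#'
#' \deqn{\ln L(\theta) = \sum_i [ y_{11i}\ln\pi_{11i} +
#'   y_{10i}\ln\pi_{10i} + y_{01i}\ln\pi_{01i} + y_{00i}\ln\pi_{00i} ],}
#' with the cells obtained from the three polynomial links through the
#' Plackett inversion (\code{\link{joint_cells}}). Each unit contributes
#' the log of exactly one cell probability.
#'
#' @param theta Parameter vector in canonical order.
#' @param data A \code{"bpblr_response"}.
#' @param design A \code{"bpblr_design"} (or \code{NULL} for the
#'   intercept-only null model).
#' @return Finite scalar log-likelihood.
#' @export
log_likelihood <- function(theta, data, design = NULL) {
  design <- as_design(design, data$n)
  if (data$n != design$n) stop("response and design row counts differ")
  pr <- model_probabilities(theta, design)
  sum(data$Y * log(pmax(pr$cells, .EPS_P)))
}

#' Analytic score of the log-likelihood
#'
#' Per-observation gradient contributions in the canonical parameter
#' order, obtained by the chain rule through the Plackett inversion.
#' Writing \eqn{c_i = y_{11i}/\pi_{11i} - y_{10i}/\pi_{10i} -
#' y_{01i}/\pi_{01i} + y_{00i}/\pi_{00i}} and
#' \eqn{\Delta_{2i} = (1/\pi_{11i} + 1/\pi_{10i} + 1/\pi_{01i} +
#' 1/\pi_{00i})^{-1}}, implicit differentiation of the odds-ratio
#' constraint gives
#' \eqn{\partial\pi_{11}/\partial\eta_3 = \Delta_2} and
#' \eqn{\partial\pi_{11}/\partial\pi_1 = \Delta_2(1/\pi_{00} +
#' 1/\pi_{10})} (symmetrically for \eqn{\pi_2}), so the per-unit score
#' with respect to \eqn{\eta_1} is
#' \eqn{\pi_1(1-\pi_1)[y_{10}/\pi_{10} - y_{00}/\pi_{00} +
#' c\,\Delta_2(1/\pi_{00} + 1/\pi_{10})]}, and with respect to
#' \eqn{\eta_3} it is \eqn{\Delta_2 c}. Slope entries are the intercept
#' entry of their block times the design feature. The result is
#' validated against a finite-difference oracle in the test suite.
#'
#' @inheritParams log_likelihood
#' @return List with \code{per_unit} (\eqn{n \times p} matrix of
#'   per-observation scores), \code{total} (its column sums, the
#'   gradient \eqn{q(\theta)}), and the per-unit factors \code{delta2}.
#' @export
score <- function(theta, data, design = NULL) {
  design <- as_design(design, data$n)
  if (data$n != design$n) stop("response and design row counts differ")
  pr <- model_probabilities(theta, design)
  C <- pmax(pr$cells, .EPS_P)
  Y <- data$Y
  r00 <- Y[, "p00"] / C[, "p00"]; r01 <- Y[, "p01"] / C[, "p01"]
  r10 <- Y[, "p10"] / C[, "p10"]; r11 <- Y[, "p11"] / C[, "p11"]
  cc <- r11 - r10 - r01 + r00
  delta2 <- 1 / (1 / C[, "p11"] + 1 / C[, "p10"] +
                 1 / C[, "p01"] + 1 / C[, "p00"])
  d11_d1 <- delta2 * (1 / C[, "p00"] + 1 / C[, "p10"])
  d11_d2 <- delta2 * (1 / C[, "p00"] + 1 / C[, "p01"])
  u1 <- pr$pi1 * (1 - pr$pi1) * ((r10 - r00) + cc * d11_d1)
  u2 <- pr$pi2 * (1 - pr$pi2) * ((r01 - r00) + cc * d11_d2)
  u3 <- delta2 * cc
  X <- design$X
  per_unit <- cbind(u1, u1 * X, u2, u2 * X, u3, u3 * X)
  colnames(per_unit) <- theta_names(design)
  list(per_unit = per_unit, total = colSums(per_unit), delta2 = delta2)
}

#' BHHH outer-product information matrix
#'
#' Sums the per-observation score outer products,
#' \eqn{B = \sum_i g_i g_i^T}: the information approximation the BHHH
#' method is built on. (A form using the outer product of the total
#' gradient would be rank one and singular for \eqn{p > 1}; the
#' per-observation sum is the estimator the method defines.)
#'
#' @param per_unit_scores \eqn{n \times p} matrix of per-observation
#'   scores, as returned in \code{score()$per_unit}.
#' @return Symmetric positive semi-definite \eqn{p \times p} matrix with
#'   attribute \code{"deficient"} flagging a numerically rank-deficient
#'   result (the fitter then falls back to a ridge).
#' @export
bhhh_information <- function(per_unit_scores) {
  G <- as.matrix(per_unit_scores)
  p <- ncol(G)
  if (nrow(G) < p)
    warning(sprintf("fewer observations (%d) than parameters (%d); information matrix is rank-deficient",
                    nrow(G), p))
  B <- crossprod(G)
  deficient <- qr(B)$rank < p
  attr(B, "deficient") <- deficient
  B
}

# intercept-only design used by the null model: zero expansion columns
null_design <- function(n) {
  structure(list(X = matrix(numeric(0), nrow = n, ncol = 0L),
                 degrees = integer(0), predictor_names = character(0),
                 n = n, standardize = FALSE, centers = NULL, scales = NULL),
            class = "bpblr_design")
}

as_design <- function(design, n) {
  if (is.null(design)) null_design(n) else design
}
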
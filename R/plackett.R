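# probability clamp applied before any logarithm, and the cap on the
# log odds ratio before exponentiation (beyond |eta3| = 35 the joint
# cells are at their boundary to machine precision)
.EPS_P <- 1e-12
.ETA3_CAP <- 35

#' Linear predictors of the three links
#'
#' Computes, per unit, \eqn{\eta_1 = \alpha_1 + \beta_1^T x^*},
#' \eqn{\eta_2 = \alpha_2 + \beta_2^T x^*} and
#' \eqn{\eta_3 = \alpha_3 + \gamma^T x^*}, where \eqn{x^*} is the
#' expanded polynomial design row.
#'
#' @param theta Numeric parameter vector in canonical order
#'   (\eqn{\alpha_1}, \eqn{\beta_1} block, \eqn{\alpha_2}, \eqn{\beta_2}
#'   block, \eqn{\alpha_3}, \eqn{\gamma} block); length must equal
#'   \code{n_parameters(design)}.
#' @param design A \code{"bpblr_design"}.
#' @return A list with numeric vectors \code{eta1}, \code{eta2},
#'   \code{eta3}, one element per unit.
#' @export
linear_predictors <- function(theta, design) {
  X <- design$X
  th <- split_theta(theta, ncol(X))
  list(eta1 = as.numeric(th$a1 + X %*% th$b1),
       eta2 = as.numeric(th$a2 + X %*% th$b2),
       eta3 = as.numeric(th$a3 + X %*% th$g))
}

#' Marginal success probabilities from the logit links
#'
#' @param eta1,eta2 Linear predictors of the two marginal logits.
#' @return List with \code{pi1}, \code{pi2}, each clamped to
#'   \eqn{[10^{-12}, 1 - 10^{-12}]} so later logarithms stay finite.
#' @export
marginal_probabilities <- function(eta1, eta2) {
  list(pi1 = pmin(pmax(stats::plogis(eta1), .EPS_P), 1 - .EPS_P),
       pi2 = pmin(pmax(stats::plogis(eta2), .EPS_P), 1 - .EPS_P))
}

#' Global odds ratio from its log link
#'
#' @param eta3 Linear predictor of the log odds ratio link; clipped to
#'   \eqn{\pm 35} before exponentiation as an overflow guard.
#' @return \eqn{\psi = \exp(\eta_3) > 0}. \eqn{\psi = 1} is independence.
#' @export
odds_ratio_link <- function(eta3) {
  exp(pmin(pmax(eta3, -.ETA3_CAP), .ETA3_CAP))
}

#' Joint 2x2 cell probabilities from marginals and the odds ratio
#'
#' Inverts the global (Plackett) odds ratio
#' \eqn{\psi = \pi_{00}\pi_{11} / (\pi_{01}\pi_{10})}: \eqn{\pi_{11}} is
#' the admissible root of a quadratic in \eqn{\pi_{11}}, computed in the
#' cancellation-free form
#' \deqn{\pi_{11} = 2\psi\pi_1\pi_2 / (a + \sqrt{a^2 + b}),}
#' with \eqn{a = 1 + (\psi-1)(\pi_1+\pi_2)} and
#' \eqn{b = -4\psi(\psi-1)\pi_1\pi_2} (algebraically identical to the
#' textbook root \eqn{(a - \sqrt{a^2+b})/(2(\psi-1))} but stable as
#' \eqn{\psi \to 1}). When \eqn{|\psi - 1| < 10^{-10}} the independence
#' product \eqn{\pi_1\pi_2} is used. The other three cells follow from
#' the marginal identities \eqn{\pi_{10} = \pi_1 - \pi_{11}},
#' \eqn{\pi_{01} = \pi_2 - \pi_{11}},
#' \eqn{\pi_{00} = 1 - \pi_1 - \pi_2 + \pi_{11}}.
#'
#' @param pi1,pi2 Marginal success probabilities in (0,1); vectors are
#'   recycled to common length.
#' @param psi Positive global odds ratio.
#' @return Numeric matrix with one row per unit and columns
#'   \code{p00}, \code{p01}, \code{p10}, \code{p11}; rows sum to 1 and
#'   every cell respects its Frechet bounds (up to the probability clamp).
#' @examples
#' joint_cells(0.4, 0.7, 1)    # p11 = 0.28
#' joint_cells(0.5, 0.5, 71)   # p11 ~= 0.44696
#' @export
joint_cells <- function(pi1, pi2, psi) {
  nn <- max(length(pi1), length(pi2), length(psi))
  pi1 <- rep_len(pmin(pmax(pi1, .EPS_P), 1 - .EPS_P), nn)
  pi2 <- rep_len(pmin(pmax(pi2, .EPS_P), 1 - .EPS_P), nn)
  psi <- rep_len(psi, nn)
  if (any(psi <= 0)) stop("'psi' must be positive")
  p11 <- numeric(nn)
  ind <- abs(psi - 1) < 1e-10
  p11[ind] <- pi1[ind] * pi2[ind]
  if (any(!ind)) {
    p1 <- pi1[!ind]; p2 <- pi2[!ind]; ps <- psi[!ind]
    a <- 1 + (ps - 1) * (p1 + p2)
    b <- -4 * ps * (ps - 1) * p1 * p2
    p11[!ind] <- 2 * ps * p1 * p2 / (a + sqrt(a * a + b))
  }
  # keep p11 inside its Frechet box so every derived cell stays >= clamp
  lo <- pmax(.EPS_P, pi1 + pi2 - 1 + .EPS_P)
  hi <- pmax(lo, pmin(pi1, pi2) - .EPS_P)
  p11 <- pmin(pmax(p11, lo), hi)
  cells <- cbind(p00 = 1 - pi1 - pi2 + p11,
                 p01 = pi2 - p11,
                 p10 = pi1 - p11,
                 p11 = p11)
  if (any(!is.finite(cells)) || any(cells < -1e-9))
    stop("internal error: invalid joint cell probabilities")
  cells
}

# eta -> (pi1, pi2, psi, cells) for every unit; the shared forward pass
model_probabilities <- function(theta, design) {
  eta <- linear_predictors(theta, design)
  marg <- marginal_probabilities(eta$eta1, eta$eta2)
  psi <- odds_ratio_link(eta$eta3)
  cells <- joint_cells(marg$pi1, marg$pi2, psi)
  list(eta = eta, pi1 = marg$pi1, pi2 = marg$pi2, psi = psi, cells = cells)
}
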
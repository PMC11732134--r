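#' Starting values for the BHHH iteration
#'
#' \eqn{(\alpha_1, \beta_1)} and \eqn{(\alpha_2, \beta_2)} come from two
#' separate univariate logistic fits of \eqn{y_1} and \eqn{y_2} on the
#' expanded design; \eqn{\alpha_3} is the log of the pooled sample odds
#' ratio (with a +0.5 continuity correction when any cell count is
#' zero); the \eqn{\gamma} block starts at zero. If a univariate fit
#' fails or separates, that block falls back to zeros with the intercept
#' at the marginal log-odds.
#'
#' @param data A \code{"bpblr_response"}.
#' @param design A \code{"bpblr_design"} or \code{NULL} (intercept-only).
#' @return Named numeric vector of length \code{3 + 3 * sum(degrees)} in
#'   canonical order.
#' @export
initialize_parameters <- function(data, design = NULL) {
  design <- as_design(design, data$n)
  m <- ncol(design$X)
  marg_fit <- function(y) {
    ab <- c(marginal_logit(y), rep(0, m))
    if (m > 0L) {
      co <- tryCatch({
        fit <- suppressWarnings(
          stats::glm.fit(cbind(1, design$X), y,
                         family = stats::binomial()))
        if (!fit$converged || any(!is.finite(fit$coefficients))) NULL
        else fit$coefficients
      }, error = function(e) NULL)
      if (!is.null(co)) ab <- co
    }
    ab
  }
  tab <- pooled_counts(data)
  a3 <- log_odds_ratio(tab)
  theta <- c(marg_fit(data$y1), marg_fit(data$y2), a3, rep(0, m))
  names(theta) <- theta_names(design)
  theta
}

marginal_logit <- function(y) {
  p <- min(max(mean(y), 1 / (4 * length(y))), 1 - 1 / (4 * length(y)))
  stats::qlogis(p)
}

pooled_counts <- function(data) {
  colSums(data$Y)  # (n00, n01, n10, n11)
}

log_odds_ratio <- function(counts) {
  if (any(counts == 0)) counts <- counts + 0.5
  log(counts["p00"] * counts["p11"] / (counts["p01"] * counts["p10"]))
}

#' Fit the bivariate polynomial binary logit model by BHHH
#'
#' Maximizes the multinomial log-likelihood with the
#' Berndt-Hall-Hall-Hausman iteration: at each step the search direction
#' is \eqn{B^{-1} q} with \eqn{q} the total score and \eqn{B} the sum of
#' per-observation score outer products, followed by step-halving so an
#' accepted step never decreases the log-likelihood. Iteration stops
#' when the parameter-change max-norm falls at or below \code{epsilon},
#' when two consecutive accepted steps leave the log-likelihood flat to
#' machine precision with the parameter change already within
#' \code{1e3 * epsilon} (relative-likelihood convergence, the usual
#' secondary rule for BHHH on statistically flat surfaces), or after
#' \code{max_iter} iterations.
#' The reported covariance matrix
#' is the inverse of the final \eqn{B}.
#'
#' @param data A \code{"bpblr_response"} (see \code{\link{response_data}}).
#' @param design A \code{"bpblr_design"} (see \code{\link{build_design}}),
#'   or \code{NULL} for the intercept-only null model.
#' @param start Optional starting parameter vector; default
#'   \code{\link{initialize_parameters}}.
#' @param epsilon Convergence tolerance on the max-norm of the parameter
#'   change (default \code{1e-6}).
#' @param max_iter Maximum BHHH iterations (default 500).
#' @param ridge Relative ridge jitter added to a singular \eqn{B}
#'   (\code{ridge * trace(B)/p}; default \code{1e-8}).
#' @param max_halvings Step-halvings allowed per iteration (default 30).
#' @return Object of class \code{"bpblr_fit"}: list with \code{theta}
#'   (named estimates), \code{loglik}, \code{deviance} (\eqn{-2\ln L}),
#'   \code{n_iter}, \code{converged}, \code{covariance}, \code{score_norm},
#'   \code{trace} (per-iteration log-likelihood and step norms),
#'   \code{degrees}, \code{n}, plus the design and data for downstream
#'   tests. Non-convergence is a reported state, not an error.
#' @examples
#' set.seed(1)
#' sim <- simulate_bpblr(n = 300, truth = c(-0.5, 1, 0.2, -0.8, 1.5, 0.5),
#'                       degrees = 1, seed = 1)
#' fit <- fit_bpblr(sim$responses, sim$design)
#' fit$converged
#' @export
fit_bpblr <- function(data, design = NULL, start = NULL,
                      epsilon = 1e-6, max_iter = 500L,
                      ridge = 1e-8, max_halvings = 30L) {
  design <- as_design(design, data$n)
  p <- n_parameters(design)
  if (data$n < p)
    warning(sprintf("n = %d units for p = %d parameters; estimates may be unstable",
                    data$n, p))
  theta <- if (is.null(start)) initialize_parameters(data, design)
           else {
             if (length(start) != p)
               stop(sprintf("start has length %d; expected %d", length(start), p))
             stats::setNames(as.numeric(start), theta_names(design))
           }
  ll <- log_likelihood(theta, data, design)
  trace <- data.frame(iter = integer(0), loglik = numeric(0),
                      step_norm = numeric(0))
  converged <- FALSE
  B <- NULL
  iter <- 0L
  singular <- FALSE
  flat_steps <- 0L
  for (iter in seq_len(max_iter)) {
    sc <- score(theta, data, design)
    B <- bhhh_information(sc$per_unit)
    dir <- solve_direction(B, sc$total, ridge)
    if (is.null(dir)) { singular <- TRUE; break }
    if (max(abs(dir)) <= epsilon) {
      # the full BHHH step already moves less than the tolerance
      trace <- rbind(trace, data.frame(iter = iter, loglik = ll,
                                       step_norm = max(abs(dir))))
      converged <- TRUE
      break
    }
    qd <- sum(sc$total * dir)  # predicted ascent rate; > 0 for p.d. B
    stp <- 1
    accepted <- FALSE
    for (h in 0:max_halvings) {
      cand <- theta + stp * dir
      ll_new <- log_likelihood(cand, data, design)
      # Armijo acceptance (with a machine-precision allowance): demand a
      # fraction of the first-order predicted gain, so overshooting full
      # steps get halved and the accepted step norm actually contracts
      # near the optimum instead of jittering
      if (is.finite(ll_new) &&
          ll_new - ll >= 1e-4 * stp * qd - 1e-12 * (1 + abs(ll))) {
        accepted <- TRUE
        break
      }
      stp <- stp / 2
    }
    if (!accepted) break  # no ascent step found: at (or stuck near) a maximum
    step_norm <- max(abs(cand - theta))
    improvement <- ll_new - ll
    theta <- cand
    ll <- ll_new
    trace <- rbind(trace, data.frame(iter = iter, loglik = ll,
                                     step_norm = step_norm))
    if (step_norm <= epsilon) { converged <- TRUE; break }
    # relative-likelihood convergence: on statistically flat surfaces
    # (small n, weakly identified association block) the outer-product
    # direction can keep the parameter change just above epsilon while
    # the likelihood is flat to machine precision; two consecutive
    # accepted-but-flat small steps are reported as convergence
    if (improvement <= 1e-10 * (1 + abs(ll)) && step_norm <= 1e3 * epsilon)
      flat_steps <- flat_steps + 1L
    else
      flat_steps <- 0L
    if (flat_steps >= 2L) { converged <- TRUE; break }
  }
  sc <- score(theta, data, design)
  B <- bhhh_information(sc$per_unit)
  covmat <- tryCatch(solve(B), error = function(e) {
    lam <- ridge * sum(diag(B)) / ncol(B)
    tryCatch(solve(B + diag(lam, ncol(B))), error = function(e2)
      matrix(NA_real_, ncol(B), ncol(B)))
  })
  dimnames(covmat) <- list(names(theta), names(theta))
  structure(list(theta = theta, loglik = ll, deviance = -2 * ll,
                 n_iter = iter, converged = converged && !singular,
                 covariance = covmat,
                 score_norm = max(abs(sc$total)),
                 trace = trace, degrees = design$degrees,
                 n = data$n, design = design, data = data),
            class = "bpblr_fit")
}

solve_direction <- function(B, q, ridge) {
  d <- tryCatch(solve(B, q), error = function(e) NULL)
  if (!is.null(d) && all(is.finite(d))) return(d)
  lam <- ridge * sum(diag(B)) / ncol(B)
  for (i in 1:6) {
    d <- tryCatch(solve(B + diag(lam, ncol(B)), q), error = function(e) NULL)
    if (!is.null(d) && all(is.finite(d))) return(d)
    lam <- lam * 100
  }
  NULL
}

#' Fit the intercept-only null model
#'
#' The three-parameter model \eqn{\mathrm{logit}(\pi_1) = \alpha_1},
#' \eqn{\mathrm{logit}(\pi_2) = \alpha_2}, \eqn{\ln\psi = \alpha_3}
#' saturates the pooled 2x2 table, so its maximum-likelihood cell
#' probabilities equal the observed cell proportions; the closed form
#' provides the start and BHHH is still run to tolerance.
#'
#' @param data A \code{"bpblr_response"}.
#' @param ... Passed to \code{\link{fit_bpblr}}.
#' @return A \code{"bpblr_fit"} with three parameters; element
#'   \code{fitted_cells} holds the common fitted (p00, p01, p10, p11).
#' @export
fit_null <- function(data, ...) {
  counts <- pooled_counts(data)
  if (sum(counts > 0) < 2L)
    stop("null fit needs units in at least two distinct response cells")
  fit <- fit_bpblr(data, design = NULL, ...)
  fit$fitted_cells <- drop(model_probabilities(fit$theta, null_design(1L))$cells)
  fit
}

#' Deviance of a fitted model
#'
#' @param object A \code{"bpblr_fit"}.
#' @param ... Unused.
#' @return \eqn{-2 \ln L(\hat\theta)}; smaller is better when comparing
#'   polynomial degrees on the same data.
#' @export
deviance.bpblr_fit <- function(object, ...) object$deviance

#' @export
logLik.bpblr_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

#' @export
coef.bpblr_fit <- function(object, ...) object$theta

#' @export
vcov.bpblr_fit <- function(object, ...) object$covariance

#' @export
print.bpblr_fit <- function(x, digits = 4, ...) {
  cat("Bivariate polynomial binary logit fit\n")
  if (length(x$degrees) > 0L)
    cat("  degrees:", paste(x$degrees, collapse = ","),
        " parameters:", length(x$theta), "\n")
  else
    cat("  intercept-only null model\n")
  cat(sprintf("  n = %d, logLik = %.*f, deviance = %.*f\n",
              x$n, digits, x$loglik, digits, x$deviance))
  cat(sprintf("  %s in %d iterations (max |score| = %.2e)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$score_norm))
  invisible(x)
}
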
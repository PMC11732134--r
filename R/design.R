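#' Polynomial power expansion of a single value
#'
#' Expands one predictor value into the power vector
#' \eqn{(x, x^2, \ldots, x^{r})} used by the polynomial link functions.
#'
#' @param x A finite numeric scalar (one unit's value of one predictor).
#' @param degree Positive integer polynomial degree \eqn{r \ge 1}.
#' @param unit,predictor Optional labels used in error messages.
#' @return Numeric vector of length \code{degree}; element \code{p} is
#'   \code{x^p}.
#' @examples
#' expand_unit(2, 3)   # 2 4 8
#' @export
expand_unit <- function(x, degree, unit = NULL, predictor = NULL) {
  if (length(degree) != 1L || is.na(degree) || degree < 1 || degree != floor(degree))
    stop("'degree' must be a single integer >= 1")
  if (length(x) != 1L || !is.finite(x)) {
    where <- paste0(
      if (!is.null(unit)) paste0(" for unit ", unit) else "",
      if (!is.null(predictor)) paste0(", predictor '", predictor, "'") else "")
    stop("non-finite predictor value", where)
  }
  x^seq_len(degree)
}

#' Build the expanded polynomial design
#'
#' Expands an \eqn{n \times k} table of raw predictors into the
#' predictor-major, power-minor column layout
#' \eqn{[x_1, x_1^2, \ldots, x_1^{r_1}, x_2, \ldots, x_k^{r_k}]}
#' used by all three link functions. The degree vector is retained so the
#' parameter count \eqn{3 + 3\sum_j r_j} and the test degrees of freedom
#' \eqn{3\sum_j r_j} can be derived from the design alone.
#'
#' @param x Data frame or numeric matrix of raw predictors (no missing
#'   values), one row per unit, one column per predictor.
#' @param degrees Integer vector of per-predictor polynomial degrees
#'   \eqn{r_j \ge 1}, one per column of \code{x}.
#' @param standardize Logical; if \code{TRUE}, each raw predictor is
#'   z-scored before powering. Raw powers are the default; standardizing
#'   improves conditioning when predictors have large means, at the cost
#'   of reporting coefficients on the standardized scale.
#' @return An object of class \code{"bpblr_design"}: a list with the
#'   expanded matrix \code{X} (\eqn{n \times \sum r_j}), \code{degrees},
#'   \code{predictor_names}, \code{n}, \code{standardize}, and (when
#'   standardized) the \code{centers} and \code{scales} used.
#' @examples
#' d <- build_design(data.frame(a = c(3, 1), b = c(2, 2)), degrees = c(1, 2))
#' d$X
#' n_parameters(d)  # 3 + 3 * 3
#' @export
build_design <- function(x, degrees, standardize = FALSE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("predictors must be numeric")
  k <- ncol(x)
  n <- nrow(x)
  if (k < 1L || n < 1L) stop("need at least one predictor and one unit")
  degrees <- check_degrees(degrees, k)
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("missing or non-finite predictor value at row %d, column %d",
                 bad[1L, 1L], bad[1L, 2L]))
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("x", seq_len(k))
  centers <- scales <- NULL
  if (standardize) {
    centers <- colMeans(x)
    scales <- apply(x, 2L, stats::sd)
    if (any(scales == 0)) stop("cannot standardize a constant predictor")
    x <- sweep(sweep(x, 2L, centers), 2L, scales, "/")
  }
  cols <- vector("list", k)
  labs <- vector("list", k)
  for (j in seq_len(k)) {
    pw <- seq_len(degrees[j])
    cols[[j]] <- outer(x[, j], pw, "^")
    labs[[j]] <- ifelse(pw == 1L, nms[j], paste0(nms[j], "^", pw))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- unlist(labs)
  structure(list(X = X, degrees = degrees, predictor_names = nms,
                 n = n, standardize = standardize,
                 centers = centers, scales = scales),
            class = "bpblr_design")
}

check_degrees <- function(degrees, k = NULL) {
  degrees <- as.integer(degrees)
  if (anyNA(degrees) || any(degrees < 1L))
    stop("every polynomial degree must be an integer >= 1")
  if (!is.null(k) && length(degrees) != k)
    stop(sprintf("degree vector has length %d but there are %d predictors",
                 length(degrees), k))
  degrees
}

#' Parameter count of the full model
#'
#' The model has three intercepts plus one slope per link and design
#' column: \eqn{3 + 3\sum_j r_j} parameters in total.
#'
#' @param design A \code{"bpblr_design"}, or an integer degree vector.
#' @return Integer parameter count.
#' @export
n_parameters <- function(design) {
  degrees <- if (inherits(design, "bpblr_design")) design$degrees
             else check_degrees(design)
  3L + 3L * sum(degrees)
}

#' @export
print.bpblr_design <- function(x, ...) {
  cat(sprintf("Polynomial design: %d units, %d predictors, %d columns\n",
              x$n, length(x$degrees), ncol(x$X)))
  cat("  degrees:", paste(x$predictor_names, x$degrees, sep = ":",
                          collapse = ", "), "\n")
  if (x$standardize) cat("  predictors z-scored before powering\n")
  invisible(x)
}

# canonical theta layout: (alpha1, beta1 block, alpha2, beta2 block,
# alpha3, gamma block); block entries follow the design column order
theta_names <- function(design) {
  m <- ncol(design$X)
  if (m == 0L) return(c("alpha1", "alpha2", "alpha3"))
  cn <- colnames(design$X)
  if (is.null(cn)) cn <- paste0("c", seq_len(m))
  c("alpha1", paste0("beta1_", cn),
    "alpha2", paste0("beta2_", cn),
    "alpha3", paste0("gamma_", cn))
}

split_theta <- function(theta, m) {
  if (length(theta) != 3L + 3L * m)
    stop(sprintf("parameter vector has length %d; expected %d (= 3 + 3*%d)",
                 length(theta), 3L + 3L * m, m))
  list(a1 = theta[1L],            b1 = theta[seq_len(m) + 1L],
       a2 = theta[m + 2L],        b2 = theta[seq_len(m) + m + 2L],
       a3 = theta[2L * m + 3L],   g  = theta[seq_len(m) + 2L * m + 3L])
}
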
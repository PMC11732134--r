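test_that("response bundle derives exact one-hot cell indicators", {
  rd <- response_data(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unname(rowSums(rd$Y)), rep(1, 4))
  expect_equal(unname(rd$Y[, "p11"]), c(1, 0, 0, 0))
  expect_equal(unname(rd$Y[, "p10"]), c(0, 1, 0, 0))
  expect_equal(unname(rd$Y[, "p01"]), c(0, 0, 1, 0))
  expect_equal(unname(rd$Y[, "p00"]), c(0, 0, 0, 1))
  expect_error(response_data(c(0, 2), c(0, 1)), "row 2")
  expect_error(response_data(0, c(0, 1)), "equal length")
})

test_that("each unit contributes the log of its observed cell", {
  # single unit with y = (1,1) under pi1 = pi2 = 0.5, psi = 71
  d <- build_design(data.frame(x = 0), 1)
  rd <- response_data(1, 1)
  theta <- c(0, 0, 0, 0, log(71), 0)
  expect_equal(log_likelihood(theta, rd, d), log(0.4469561),
               tolerance = 1e-6)
  # a near-degenerate fit puts the log-likelihood near zero
  theta_sat <- c(30, 0, 30, 0, 0, 0)
  expect_equal(log_likelihood(theta_sat, rd, d), 0, tolerance = 1e-8)
})

test_that("intercept-only parameters matching the pooled table give the saturated value", {
  rd <- responses_from_counts(poverty_2x2_counts())
  counts <- c(73, 5, 7, 34)
  theta <- c(qlogis(41 / 119), qlogis(39 / 119), log(73 * 34 / (5 * 7)))
  ll <- log_likelihood(theta, rd)
  expect_equal(ll, sum(counts * log(counts / 119)), tolerance = 1e-9)
})

test_that("log-likelihood is invariant under permutation of units", {
  cs <- random_case(11)
  perm <- sample(cs$sim$responses$n)
  rd_p <- response_data(cs$sim$responses$y1[perm], cs$sim$responses$y2[perm])
  d_p <- build_design(cs$sim$predictors[perm, , drop = FALSE],
                      cs$sim$degrees)
  expect_equal(log_likelihood(cs$theta, rd_p, d_p),
               log_likelihood(cs$theta, cs$sim$responses, cs$sim$design))
})

test_that("analytic score equals the finite-difference gradient", {
  for (s in 1:12) {
    cs <- random_case(100 + s)
    sc <- score(cs$theta, cs$sim$responses, cs$sim$design)
    ng <- num_gradient(cs$theta, cs$sim$responses, cs$sim$design)
    expect_equal(sc$total, ng, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("score rows carry the block structure and sum to the total", {
  cs <- random_case(42)
  sc <- score(cs$theta, cs$sim$responses, cs$sim$design)
  expect_lt(max(abs(colSums(sc$per_unit) - sc$total)), 1e-10)
  m <- ncol(cs$sim$design$X)
  # slope entries are the intercept entry of their block times the feature
  for (j in seq_len(m)) {
    expect_equal(sc$per_unit[, 1 + j],
                 sc$per_unit[, 1] * cs$sim$design$X[, j], ignore_attr = TRUE)
    expect_equal(sc$per_unit[, 2 * m + 3 + j],
                 sc$per_unit[, 2 * m + 3] * cs$sim$design$X[, j],
                 ignore_attr = TRUE)
  }
  # only terms tied to the observed cell are nonzero for a single unit
  d1 <- build_design(data.frame(x = 0.7), 1)
  sc1 <- score(c(0.1, 0.2, -0.1, 0.3, 0.5, -0.2), response_data(1, 1), d1)
  expect_equal(unname(sc1$total[2]), unname(sc1$total[1]) * 0.7)
})

test_that("score vanishes at the null-model maximum", {
  rd <- responses_from_counts(poverty_2x2_counts())
  theta_hat <- fit_null(rd)$theta
  expect_lt(max(abs(score(theta_hat, rd)$total)), 1e-6)
})

test_that("expected gamma-score is zero under independence", {
  set.seed(99)
  truth <- c(-0.3, 0.5, 0.4, -0.4, 0, 0)  # psi = 1, gamma = 0
  sim <- simulate_bpblr(n = 10000, truth = truth, degrees = 1, seed = 99)
  sc <- score(truth, sim$responses, sim$design)
  g_scores <- sc$per_unit[, c("alpha3", "gamma_x1")]
  mean_se <- apply(g_scores, 2, function(g) abs(mean(g)) / (sd(g) / sqrt(length(g))))
  expect_true(all(mean_se < 3))
})

test_that("the information matrix is the per-observation outer-product sum", {
  Z <- matrix(0, 5, 3)
  expect_equal(unname(bhhh_information(Z)), matrix(0, 3, 3), ignore_attr = TRUE)
  g <- matrix(c(1, 2, -1), 1, 3)
  expect_warning(B1 <- bhhh_information(g), "rank-deficient")
  expect_equal(unname(B1), crossprod(g), ignore_attr = TRUE)
  expect_true(attr(B1, "deficient"))
  cs <- random_case(17, n = 60)
  G <- score(cs$theta, cs$sim$responses, cs$sim$design)$per_unit
  B <- bhhh_information(G)
  expect_equal(unname(B), unname(crossprod(G)), ignore_attr = TRUE)
  expect_true(isSymmetric(B))
  expect_true(all(eigen(B, symmetric = TRUE, only.values = TRUE)$values > -1e-8))
})

test_that("inverse-information SEs track the sampling spread of the MLE", {
  # Monte-Carlo oracle at small scale: one large fit's SEs should be of
  # the same order as the empirical SD over independent replicates
  truth <- moderate_truth()
  reps <- 40
  est <- matrix(NA_real_, reps, length(truth))
  se1 <- NULL
  for (r in seq_len(reps)) {
    sim <- simulate_bpblr(n = 500, truth = truth, degrees = c(1, 1),
                          seed = 5000 + r)
    fit <- fit_bpblr(sim$responses, sim$design)
    if (r == 1) se1 <- sqrt(diag(fit$covariance))
    if (fit$converged) est[r, ] <- fit$theta
  }
  emp_sd <- apply(est, 2, sd, na.rm = TRUE)
  expect_true(all(se1 / emp_sd > 0.5 & se1 / emp_sd < 2))
})
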
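test_that("independence tests reproduce the observed-table statistics", {
  res <- independence_tests(poverty_2x2_counts())
  expect_equal(res$pearson$statistic, 71.414, tolerance = 1e-4)
  expect_equal(res$lr$statistic, 75.927, tolerance = 1e-4)
  expect_equal(res$pearson$df, 1L)
  expect_equal(res$lr$df, 1L)
  expect_true(res$pearson$reject && res$lr$reject)
  # independent cross-check against the stock Pearson test
  ref <- suppressWarnings(chisq.test(poverty_2x2_counts(), correct = FALSE))
  expect_equal(res$pearson$statistic, unname(ref$statistic))
})

test_that("independence tests vanish on exactly proportional tables", {
  res <- independence_tests(matrix(10, 2, 2))
  expect_equal(res$pearson$statistic, 0)
  expect_equal(res$lr$statistic, 0)
  res <- independence_tests(matrix(c(20, 10, 40, 20), 2, 2, byrow = TRUE))
  expect_equal(res$pearson$statistic, 0, tolerance = 1e-12)
})

test_that("independence tests validate their input", {
  expect_error(independence_tests(matrix(c(5, 5, 0, 0), 2, 2, byrow = TRUE)),
               "margin")
  expect_error(independence_tests(c(1.5, 2, 3, 4)), "integer")
  expect_error(independence_tests(c(-1, 2, 3, 4)), "nonnegative")
})

test_that("chi-square critical values match published tables", {
  expect_equal(chi_square_critical(0.05, 18), 28.8693, tolerance = 1e-4)
  expect_equal(chi_square_critical(0.05, 1), 3.8415, tolerance = 1e-4)
  # quantile / upper-tail probability round trip
  for (df in c(1, 6, 18)) {
    crit <- chi_square_critical(0.05, df)
    expect_equal(pchisq(crit, df, lower.tail = FALSE), 0.05)
  }
  expect_error(chi_square_critical(1.2, 3), "alpha")
  expect_error(chi_square_critical(0.05, 0), "df")
})

test_that("the simultaneous likelihood ratio test has df = 3 * sum(degrees)", {
  sim <- simulate_bpblr(n = 150, truth = moderate_truth(), degrees = c(1, 1),
                        seed = 77)
  full <- fit_bpblr(sim$responses, sim$design)
  null <- fit_null(sim$responses)
  tst <- mlrt_simultaneous(full, null)
  expect_equal(tst$df, 6L)
  expect_equal(tst$statistic, null$deviance - full$deviance, tolerance = 1e-10)
  expect_equal(tst$p_value, pchisq(tst$statistic, 6, lower.tail = FALSE))
  expect_equal(tst$critical_value, qchisq(0.95, 6))
  # single predictor: df 3 at degree 1, df 6 at degree 2
  d1 <- build_design(sim$predictors[1], 1)
  expect_equal(mlrt_simultaneous(fit_bpblr(sim$responses, d1), null)$df, 3L)
  d2 <- build_design(sim$predictors[1], 2)
  expect_equal(mlrt_simultaneous(fit_bpblr(sim$responses, d2), null)$df, 6L)
})

test_that("a four-predictor design with degrees (2,1,1,2) yields df = 18", {
  sim <- paper_like_scenario(seed = 3)
  design <- build_design(sim$predictors, c(2, 1, 1, 2), standardize = TRUE)
  full <- fit_bpblr(sim$responses, design)
  tst <- mlrt_simultaneous(full, fit_null(sim$responses))
  expect_equal(tst$df, 18L)
})

test_that("a full fit equal to the null gives a zero statistic and p = 1", {
  rd <- responses_from_counts(poverty_2x2_counts())
  null <- fit_null(rd)
  # full-model parameters with every slope zero and intercepts at the
  # null optimum: the two likelihoods coincide
  d <- build_design(data.frame(x = rnorm(rd$n)), 1)
  th <- null$theta
  full <- fit_bpblr(rd, d, start = c(th[1], 0, th[2], 0, th[3], 0),
                    max_iter = 0L)
  tst <- mlrt_simultaneous(full, null)
  expect_equal(tst$statistic, 0)
  expect_equal(tst$p_value, 1)
  expect_equal(tst$df, 3L)
})

test_that("Wald tests transform estimates and SEs to normal p-values", {
  sim <- simulate_bpblr(n = 600, truth = moderate_truth(), degrees = c(1, 1),
                        seed = 88)
  fit <- fit_bpblr(sim$responses, sim$design)
  w <- wald_partial_tests(fit)
  expect_equal(w$z, w$estimate / w$se)
  expect_equal(w$p_value, 2 * pnorm(-abs(w$z)))
  # closed-form anchors of the normal reference
  fit2 <- fit
  fit2$theta[1] <- 0
  expect_equal(wald_partial_tests(fit2)$p_value[1], 1)
  fit2$theta[1] <- 1.96 * sqrt(fit$covariance[1, 1])
  expect_equal(wald_partial_tests(fit2)$p_value[1], 0.05, tolerance = 1e-3)
  # non-positive variance entries are flagged, not propagated
  fit2$covariance[1, 1] <- -1
  w2 <- wald_partial_tests(fit2)
  expect_true(w2$flagged[1])
  expect_true(is.na(w2$se[1]))
})

test_that("VIF matches its closed forms", {
  set.seed(123)
  n <- 400
  x1 <- rnorm(n)
  x_orth <- cbind(a = x1, b = rnorm(n))
  v <- vif(x_orth)
  expect_equal(v$vif, c(1, 1), tolerance = 0.05)
  expect_false(any(v$flagged))
  # duplicated predictor: infinite, flagged
  v <- vif(cbind(a = x1, b = x1, c = rnorm(n)))
  expect_true(is.infinite(v$vif[1]) && is.infinite(v$vif[2]))
  expect_true(all(v$flagged[1:2]))
  # known correlation rho = 0.9 -> VIF ~ 1/(1 - 0.81)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  v <- vif(cbind(a = x1, b = x2))
  expect_equal(v$vif, rep(1 / (1 - 0.81), 2), tolerance = 0.25)
  expect_error(vif(matrix(rnorm(10), 10, 1)), "two predictors")
})
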
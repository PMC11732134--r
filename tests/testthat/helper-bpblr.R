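# central finite-difference gradient of the log-likelihood; the
# independent oracle the analytic score is validated against
num_gradient <- function(theta, data, design, h = 1e-6) {
  vapply(seq_along(theta), function(i) {
    hp <- h * max(1, abs(theta[i]))
    tp <- tm <- theta
    tp[i] <- tp[i] + hp
    tm[i] <- tm[i] - hp
    (log_likelihood(tp, data, design) -
       log_likelihood(tm, data, design)) / (2 * hp)
  }, numeric(1))
}

# small random dataset + random parameters for property loops; the
# predictor range and parameter spread keep every unit away from the
# probability clamps, where the likelihood is genuinely non-smooth and
# a derivative comparison would be meaningless
random_case <- function(seed, n = 40, k = 2, max_degree = 3) {
  set.seed(seed)
  degrees <- sample.int(max_degree, k, replace = TRUE)
  spec <- data.frame(name = paste0("x", seq_len(k)), mean = 0, sd = 1,
                     min = -1.5, max = 1.5)
  truth <- stats::rnorm(3 + 3 * sum(degrees), 0, 0.3)
  sim <- simulate_bpblr(n = n, truth = truth, degrees = degrees,
                        spec = spec, seed = seed)
  theta <- stats::rnorm(length(truth), 0, 0.3)
  list(sim = sim, theta = theta)
}

# a moderate-effect degree-1 truth over two predictors, used by the
# recovery and calibration simulations
moderate_truth <- function() {
  c(-0.5, 0.8, -0.3,   # alpha1, beta1
     0.2, 0.5,  0.1,   # alpha2, beta2
     1.2, 0.4, -0.2)   # alpha3, gamma
}
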
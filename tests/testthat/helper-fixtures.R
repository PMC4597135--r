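# Shared fixtures and independent oracles for the test suite.

# simulate paired error vectors straight from the observer equations,
# bypassing the package's trial plumbing (independent generative route)
sim_errors <- function(n, sigma_prior, sigma_evidence, shift = 0,
                       sigma_performance = 40, seed = 1) {
  set.seed(seed)
  w <- sigma_evidence^2 / (sigma_prior^2 + sigma_evidence^2)
  p <- rnorm(n, 0, sigma_performance)
  est <- -w * p + (1 - w) * shift + rnorm(n, 0, (1 - w) * sigma_evidence)
  list(perf = p, est = est, w = w)
}

# brute-force OLS via the normal equations (oracle for regression fits)
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(intercept = beta[1], slope = beta[2],
       resid_sd_ml = sqrt(sum(res^2) / length(y)))
}

# brute-force Gaussian log-likelihood (oracle for loglik_bayes)
loglik_oracle <- function(sigma_prior, sigma_evidence, shift, perf, est) {
  w <- sigma_evidence^2 / (sigma_prior^2 + sigma_evidence^2)
  mu <- -w * perf + (1 - w) * shift
  s <- (1 - w) * sigma_evidence
  sum(-0.5 * log(2 * pi) - log(s) - (est - mu)^2 / (2 * s^2))
}

# brute-force partial Spearman: explicit rank regression residuals
partial_spearman_oracle <- function(x, y, z) {
  z <- as.matrix(as.data.frame(z))
  zr <- apply(z, 2, rank)
  rx <- residuals(lm(rank(x) ~ zr))
  ry <- residuals(lm(rank(y) ~ zr))
  cor(rx, ry)
}

# a minimal well-formed trial table built by hand
tiny_trials <- function(est_times, subject_id = "s1", group = "patient",
                        target_x = 512) {
  n <- length(est_times)
  data.frame(subject_id = subject_id, group = group, block = 1L,
             trial_index = seq_len(n), target_x = target_x,
             stop_x = target_x + seq(-20, 20, length.out = n),
             point_x = target_x + seq(-10, 10, length.out = n),
             stop_time = 1.5, estimation_time = est_times,
             skipped = FALSE, n_sweeps = 1L, stringsAsFactors = FALSE)
}
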
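test_that("predictive law matches the cue-integration arithmetic", {
  # sigma_p = 3, sigma_e = 4 => w = 16/25; p = 25 => mean -16, sd 1.44
  law <- predictive_law(25, bayes_params(3, 4))
  expect_equal(law$mean, -16)
  expect_equal(law$sd, 1.44)

  # w = 0.5, shift 0, p = 10 => mean -5
  expect_equal(predictive_law(10, bayes_params(20, 20))$mean, -5)

  # evidence-only limit: w -> 0 => mean -> shift, sd -> sigma_e
  law0 <- predictive_law(10, bayes_params(1e6, 5, shift_evidence = 7))
  expect_equal(law0$mean, 7, tolerance = 1e-3)
  expect_equal(law0$sd, 5, tolerance = 1e-3)
})

test_that("log-likelihood matches a brute-force oracle and is additive", {
  # single observation at the predictive mode with unit predictive sd
  par <- bayes_params(1, 1, 0)        # w = 0.5, sd = 0.5 * 1 = 0.5
  par2 <- bayes_params(sqrt(3), 3, 0) # w = 0.75, sd = 0.25 * 3 = 0.75
  # construct unit predictive sd: (1 - w) * sigma_e = 1 with w = 0.5
  par_unit <- bayes_params(2, 2, 0)
  law <- predictive_law(4, par_unit)
  expect_equal(law$sd, 1)
  ll <- loglik_bayes(par_unit, 4, law$mean, model_id = 1)
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-12)

  set.seed(21)
  perf <- rnorm(50, 0, 30)
  est <- rnorm(50, 0, 15)
  for (shift in c(0, -20)) {
    pr <- bayes_params(15, 25, shift)
    got <- loglik_bayes(pr, perf, est, model_id = 2)
    want <- loglik_oracle(15, 25, shift, perf, est)
    expect_equal(got, want, tolerance = 1e-10)
  }

  # duplicating the dataset doubles the log-likelihood
  pr <- bayes_params(15, 25, -5)
  one <- loglik_bayes(pr, perf, est)
  two <- loglik_bayes(pr, c(perf, perf), c(est, est))
  expect_equal(two, 2 * one, tolerance = 1e-10)

  expect_error(loglik_bayes(bayes_params(2, 2, 3), perf, est, model_id = 1),
               "shift")
})

test_that("BIC follows the natural-log definition", {
  expect_equal(bic(0, 2, 1), 0)
  expect_equal(bic(-100, 3, 100), 3 * log(100) + 200)
  expect_equal(bic(-50, 3, 77) - bic(-50, 2, 77), log(77))
  expect_error(bic(0, 2, 0), "n")
})

test_that("closed form inverts the regression parameterization", {
  # exact line est = -0.5 * p + 1 plus residuals of ML sd 2
  # => w = 0.5, sigma_e = 4, sigma_p = 4, shift = 2
  p <- rep(c(-10, 10), each = 4)
  resid <- rep(c(-2, 2), 4)            # mean 0, ML sd 2, orthogonal to p
  est <- -0.5 * p + 1 + resid
  f <- closed_form_fit(p, est, model_id = 2)
  expect_equal(f$params$w, 0.5, tolerance = 1e-12)
  expect_equal(f$params$sigma_evidence, 4, tolerance = 1e-12)
  expect_equal(f$params$sigma_prior, 4, tolerance = 1e-12)
  expect_equal(f$params$shift_evidence, 2, tolerance = 1e-12)
  expect_false(f$boundary)
  expect_equal(f$k_params, 3L)
  expect_equal(f$bic, 3 * log(8) - 2 * f$loglik)

  # zero intercept data: shift estimate 0
  est0 <- -0.5 * p + resid
  f0 <- closed_form_fit(p, est0, model_id = 2)
  expect_equal(f0$params$shift_evidence, 0, tolerance = 1e-12)

  # model 1 forces shift 0 and uses regression through the origin
  f1 <- closed_form_fit(p, est0, model_id = 1)
  expect_equal(f1$params$shift_evidence, 0)
  expect_equal(f1$k_params, 2L)
  b0 <- sum(p * est0) / sum(p^2)
  expect_equal(f1$params$w, -b0, tolerance = 1e-12)

  # positive slope (no bias toward target): boundary handling
  fb <- closed_form_fit(p, 0.2 * p + resid, model_id = 2)
  expect_true(fb$boundary)
  expect_equal(fb$params$w, 1e-3, tolerance = 1e-12)
  expect_gt(fb$params$sigma_prior / fb$params$sigma_evidence, 10)

  expect_error(closed_form_fit(c(1, 2, 3), c(1, 2, 3)), ">= 4")
  expect_error(closed_form_fit(rep(1, 8), rnorm(8)), "identical")
})

test_that("numerical MLE agrees with the closed form on interior data", {
  set.seed(31)
  for (i in 1:25) {
    d <- sim_errors(60, sigma_prior = runif(1, 5, 40),
                    sigma_evidence = runif(1, 5, 40),
                    shift = rnorm(1, 0, 15), seed = 1000 + i)
    for (model in 1:2) {
      cf <- closed_form_fit(d$perf, d$est, model)
      if (cf$boundary) next
      ml <- fit_mle(d$perf, d$est, model)
      expect_gte(ml$loglik, cf$loglik - 1e-6)
      expect_lt(abs(ml$loglik - cf$loglik), 1e-6)
      expect_lt(abs(ml$params$sigma_prior / cf$params$sigma_prior - 1), 1e-4)
      expect_lt(abs(ml$params$sigma_evidence / cf$params$sigma_evidence - 1),
                1e-4)
    }
  }
})

test_that("parameters are recovered from large simulated datasets", {
  d <- sim_errors(1e4, sigma_prior = 15, sigma_evidence = 25, shift = -20,
                  seed = 99)
  f <- fit_mle(d$perf, d$est, 2)
  expect_lt(abs(f$params$sigma_prior / 15 - 1), 0.05)
  expect_lt(abs(f$params$sigma_evidence / 25 - 1), 0.05)
  expect_lt(abs(f$params$shift_evidence / -20 - 1), 0.05)

  # smallest legal input still returns a finite fit
  f4 <- fit_mle(c(-2, -1, 1, 2), c(1.5, 0.4, -0.6, -1.6), 2)
  expect_true(is.finite(f4$bic))
})

test_that("translation of all positions leaves the model-2 fit unchanged", {
  # errors are relative quantities: shifting target/stop/point together is
  # an exact no-op on the likelihood path
  p <- subject_params("s", "control", skip_prob = 0)
  tr <- simulate_subject(p, 200, seed = 12)
  tr2 <- tr
  tr2$target_x <- tr2$target_x + 137
  tr2$stop_x <- tr2$stop_x + 137
  tr2$point_x <- tr2$point_x + 137
  e1 <- compute_errors(tr); e2 <- compute_errors(tr2)
  f1 <- fit_mle(e1$performance_error, e1$estimation_error, 2)
  f2 <- fit_mle(e2$performance_error, e2$estimation_error, 2)
  expect_equal(f1$loglik, f2$loglik)
  expect_equal(f1$params$shift_evidence, f2$params$shift_evidence)
})

test_that("model selection prefers lower BIC with parsimony tie-break", {
  mk <- function(model, ll, n) {
    pars <- bayes_params(10, 10, if (model == 2) -5 else 0)
    structure(list(model_id = model, params = pars, loglik = ll,
                   bic = bic(ll, if (model == 1) 2 else 3, n),
                   n_trials = n, k_params = if (model == 1) 2L else 3L,
                   boundary = FALSE, converged = TRUE),
              class = "fit_result")
  }
  n <- 100
  # equal BIC: winner model 1
  ll2 <- -50; ll1 <- (3 * log(n) - 2 * ll2 - 2 * log(n)) / -2
  tie <- select_model(mk(1, ll1, n), mk(2, ll2, n))
  expect_equal(tie$delta_bic, 0)
  expect_equal(tie$winner, 1L)
  expect_false(tie$strong)

  # bic2 = bic1 - 7: winner 2, strong
  f1 <- mk(1, -60, n)
  ll2b <- -(f1$bic - 7 - 3 * log(n)) / 2
  ch <- select_model(f1, mk(2, ll2b, n))
  expect_equal(ch$winner, 2L)
  expect_true(ch$strong)

  expect_error(select_model(mk(1, -10, 50), mk(2, -10, 60)), "same data")
})

test_that("BIC winner tracks the generating model", {
  # scaled-down version of the full acceptance sweep (20 replicates here)
  pick_winner <- function(shift, seed) {
    d <- sim_errors(104, sigma_prior = 20, sigma_evidence = 20,
                    shift = shift, seed = seed)
    fit_subject(d$perf, d$est)$choice$winner
  }
  w0 <- vapply(1:20, function(s) pick_winner(0, s), integer(1))
  w30 <- vapply(1:20, function(s) pick_winner(-30, 100 + s), integer(1))
  expect_gte(mean(w0 == 1L), 0.9)
  expect_gte(mean(w30 == 2L), 0.9)
})
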
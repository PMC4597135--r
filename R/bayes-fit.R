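#' Observer model parameters
#'
#' Parameters of the Gaussian cue-integration observer: a prior over
#' outcomes centred on the target with SD `sigma_prior`, sensory evidence
#' centred on the true stopping position (plus a constant `shift_evidence`)
#' with SD `sigma_evidence`. The integration weight
#' `w = sigma_evidence^2 / (sigma_prior^2 + sigma_evidence^2)` is the share
#' of the percept pulled toward the target.
#'
#' @param sigma_prior,sigma_evidence SDs in pixels, > 0.
#' @param shift_evidence Signed shift in pixels (0 in the constrained
#'   2-parameter model).
#' @return A list with class `"bayes_params"` including the derived `w`.
#' @export
bayes_params <- function(sigma_prior, sigma_evidence, shift_evidence = 0) {
  check_positive(sigma_prior, "sigma_prior")
  check_positive(sigma_evidence, "sigma_evidence")
  w <- sigma_evidence^2 / (sigma_prior^2 + sigma_evidence^2)
  structure(list(sigma_prior = sigma_prior, sigma_evidence = sigma_evidence,
                 shift_evidence = shift_evidence, w = w),
            class = "bayes_params")
}

#' Predictive distribution of the estimation error
#'
#' Given a trial's performance error `p` (stopping position relative to the
#' target), the observer's reported error is Gaussian. In target-centred
#' coordinates the percept is `w * 0 + (1 - w) * e` with evidence
#' `e ~ N(p + shift, sigma_evidence^2)`, so the estimation error
#' (percept minus `p`) has mean `-w * p + (1 - w) * shift` and SD
#' `(1 - w) * sigma_evidence`.
#'
#' @param p Performance error(s), px.
#' @param params A [bayes_params()] object.
#' @return A list with vectors `mean` and scalar `sd` (px).
#' @examples
#' predictive_law(25, bayes_params(3, 4))  # mean -16, sd 1.44
#' @export
predictive_law <- function(p, params) {
  if (!inherits(params, "bayes_params")) {
    stop_param("`params` must be a bayes_params object")
  }
  w <- params$w
  list(mean = -w * p + (1 - w) * params$shift_evidence,
       sd = (1 - w) * params$sigma_evidence)
}

#' Log-likelihood of an error dataset under the observer model
#'
#' Sum over trials of the Gaussian log-density of each estimation error
#' under [predictive_law()]. Model 1 is the constrained 2-parameter model
#' (shift fixed at 0); model 2 frees the shift.
#'
#' @param params A [bayes_params()] object. For `model_id = 1` its shift
#'   must be 0.
#' @param perf_errors,est_errors Paired error vectors (px), >= 1 trial.
#' @param model_id 1 or 2.
#' @return Log-likelihood in nats.
#' @export
loglik_bayes <- function(params, perf_errors, est_errors, model_id = 2) {
  if (length(perf_errors) < 1L ||
      length(perf_errors) != length(est_errors)) {
    stop_param("need >= 1 paired error observations")
  }
  if (model_id == 1 && params$shift_evidence != 0) {
    stop_param("model 1 requires shift_evidence = 0")
  }
  law <- predictive_law(perf_errors, params)
  if (law$sd < 1e-12) {
    stop_param("predictive SD underflow ((1-w)*sigma_evidence ~ 0); ",
               "bound sigma parameters away from the edges")
  }
  sum(dnorm(est_errors, mean = law$mean, sd = law$sd, log = TRUE))
}

#' Bayesian Information Criterion
#'
#' `k * ln(n) - 2 * loglik` (natural-log convention).
#'
#' @param loglik Log-likelihood in nats.
#' @param k Number of free parameters.
#' @param n Number of observations (>= 1).
#' @return BIC in nats.
#' @export
bic <- function(loglik, k, n) {
  if (n < 1) stop_param("n must be >= 1")
  k * log(n) - 2 * loglik
}

# Map the regression parameterization (slope b, intercept a, ML residual sd)
# to observer parameters. Identified quantities are (w, (1-w)*shift,
# (1-w)*sigma_e); the map back to (sigma_p, sigma_e, shift) is bijective on
# w in (0,1).
regression_to_params <- function(b, a, resid_sd_ml,
                                 w_eps = 1e-3, sigma_bounds = c(1e-3, 1e4)) {
  w_raw <- -b
  boundary <- w_raw <= 0 || w_raw >= 1
  w <- min(max(w_raw, w_eps), 1 - w_eps)
  shift <- a / (1 - w)
  sigma_e <- resid_sd_ml / (1 - w)
  if (sigma_e < sigma_bounds[1] || sigma_e > sigma_bounds[2]) {
    sigma_e <- min(max(sigma_e, sigma_bounds[1]), sigma_bounds[2])
    boundary <- TRUE
  }
  sigma_p <- sigma_e * sqrt((1 - w) / w)
  if (sigma_p < sigma_bounds[1] || sigma_p > sigma_bounds[2]) {
    sigma_p <- min(max(sigma_p, sigma_bounds[1]), sigma_bounds[2])
    boundary <- TRUE
  }
  list(sigma_prior = sigma_p, sigma_evidence = sigma_e, shift = shift,
       boundary = boundary)
}

fit_result <- function(model_id, params, loglik, n, boundary, converged) {
  k <- if (model_id == 1) 2L else 3L
  structure(list(model_id = as.integer(model_id), params = params,
                 loglik = loglik, bic = bic(loglik, k, n),
                 n_trials = as.integer(n), k_params = k,
                 boundary = boundary, converged = converged),
            class = "fit_result")
}

#' Closed-form maximum-likelihood fit via the regression parameterization
#'
#' The Gaussian observer likelihood is a linear regression in disguise: the
#' estimation error has conditional mean `-w * p + (1 - w) * shift` and
#' constant SD, so the OLS slope `b`, intercept `a` and ML residual SD
#' `s = sqrt(RSS/n)` are the MLEs of `(-w, (1 - w) * shift, (1 - w) *
#' sigma_e)`. Inverting: `w = -b`, `shift = a / (1 - w)`,
#' `sigma_e = s / (1 - w)`, `sigma_p = sigma_e * sqrt((1 - w) / w)`.
#' Model 1 uses regression through the origin (shift fixed at 0).
#'
#' When the slope falls outside `(-1, 0)` (no graded bias toward the
#' target), the mapping diverges; `w` is clipped into `[1e-3, 1 - 1e-3]` and
#' the fit is flagged `boundary = TRUE`.
#'
#' @param perf_errors,est_errors Paired error vectors, >= 4 trials.
#' @param model_id 1 (constrained, 2 parameters) or 2 (evidence shift,
#'   3 parameters).
#' @param sigma_bounds Admissible range for both SDs (px).
#' @return A `fit_result`: `model_id`, `params` ([bayes_params()]),
#'   `loglik`, `bic`, `n_trials`, `k_params`, `boundary`, `converged`.
#' @export
closed_form_fit <- function(perf_errors, est_errors, model_id = 2,
                            sigma_bounds = c(1e-3, 1e4)) {
  n <- length(perf_errors)
  if (n < 4L) stop_param("need >= 4 trials to fit")
  if (length(est_errors) != n) stop_param("error vectors differ in length")
  if (var(perf_errors) == 0) {
    stop_param("performance errors are all identical; fit undefined")
  }
  if (model_id == 2) {
    reg <- fit_subject_regression(perf_errors, est_errors)
    b <- reg$slope; a <- reg$intercept; s <- reg$resid_sd_ml
  } else if (model_id == 1) {
    b <- sum(perf_errors * est_errors) / sum(perf_errors^2)
    a <- 0
    s <- sqrt(sum((est_errors - b * perf_errors)^2) / n)
  } else stop_param("model_id must be 1 or 2")
  m <- regression_to_params(b, a, s, sigma_bounds = sigma_bounds)
  shift <- if (model_id == 1) 0 else m$shift
  params <- bayes_params(m$sigma_prior, m$sigma_evidence, shift)
  ll <- loglik_bayes(params, perf_errors, est_errors, model_id)
  fit_result(model_id, params, ll, n, m$boundary, converged = TRUE)
}

#' Numerical maximum-likelihood fit of the observer model
#'
#' Maximizes [loglik_bayes()] over `(log sigma_prior, log sigma_evidence[,
#' shift])` with L-BFGS-B, initialized from [closed_form_fit()]. The
#' optimization is deterministic (fixed start, no random restarts). Because
#' the closed form is the exact MLE whenever the OLS slope is interior, the
#' numerical fit serves as a cross-check and handles boundary cases; the
#' returned log-likelihood is never below the closed form's by more than
#' 1e-6.
#'
#' @inheritParams closed_form_fit
#' @param shift_bounds Admissible range for the shift (px), model 2 only.
#' @return A `fit_result` (see [closed_form_fit()]); `converged = FALSE`
#'   with a warning if the optimizer reports failure.
#' @export
fit_mle <- function(perf_errors, est_errors, model_id = 2,
                    sigma_bounds = c(1e-3, 1e4),
                    shift_bounds = c(-5e3, 5e3)) {
  cf <- closed_form_fit(perf_errors, est_errors, model_id,
                        sigma_bounds = sigma_bounds)
  log_b <- log(sigma_bounds)
  start <- c(log(cf$params$sigma_prior), log(cf$params$sigma_evidence))
  lower <- c(log_b[1], log_b[1]); upper <- c(log_b[2], log_b[2])
  if (model_id == 2) {
    start <- c(start, cf$params$shift_evidence)
    lower <- c(lower, shift_bounds[1]); upper <- c(upper, shift_bounds[2])
  }
  start <- pmin(pmax(start, lower), upper)
  negll <- function(theta) {
    par <- bayes_params(exp(theta[1]), exp(theta[2]),
                        if (model_id == 2) theta[3] else 0)
    -loglik_bayes(par, perf_errors, est_errors, model_id)
  }
  opt <- optim(start, negll, method = "L-BFGS-B", lower = lower,
               upper = upper, control = list(maxit = 500))
  ok <- opt$convergence == 0L
  ll_opt <- -opt$value
  # keep the optimizer's answer only when it genuinely improves on the
  # closed form; a line-search failure at an already-optimal start is benign
  if (ll_opt > cf$loglik + 1e-8) {
    if (!ok) {
      warning("MLE did not converge (optim code ", opt$convergence, "): ",
              opt$message, call. = FALSE)
    }
    theta <- opt$par
    params <- bayes_params(exp(theta[1]), exp(theta[2]),
                           if (model_id == 2) theta[3] else 0)
    at_edge <- any(abs(theta[1:2] - log_b[1]) < 1e-8) ||
      any(abs(theta[1:2] - log_b[2]) < 1e-8)
    fit_result(model_id, params, ll_opt, length(perf_errors),
               boundary = at_edge || cf$boundary, converged = ok)
  } else {
    # closed form already optimal (interior case); keep it
    cf
  }
}

#' Compare the two observer models by BIC
#'
#' The lower BIC wins; ties go to model 1 (fewer parameters). The difference
#' is labelled "strong" evidence when it exceeds `strong_threshold` (6 by
#' convention).
#'
#' @param fit1,fit2 `fit_result`s for model 1 and model 2 on the same data.
#' @param strong_threshold BIC difference for the strong-evidence label.
#' @return A list: `winner` (1 or 2), `delta_bic` (`bic1 - bic2`; positive
#'   favors model 2), `strong`.
#' @export
select_model <- function(fit1, fit2, strong_threshold = 6) {
  if (fit1$model_id != 1L || fit2$model_id != 2L) {
    stop_param("pass model-1 then model-2 fits")
  }
  if (fit1$n_trials != fit2$n_trials) {
    stop_param("fits are not on the same data (n differs)")
  }
  delta <- fit1$bic - fit2$bic
  list(winner = if (delta > 0) 2L else 1L,
       delta_bic = delta,
       strong = abs(delta) > strong_threshold)
}

#' Fit both observer models to one subject and select by BIC
#'
#' @inheritParams fit_mle
#' @param strong_threshold Passed to [select_model()].
#' @return A list with `fit1`, `fit2` and `choice` (from [select_model()]).
#' @export
fit_subject <- function(perf_errors, est_errors,
                        sigma_bounds = c(1e-3, 1e4),
                        shift_bounds = c(-5e3, 5e3),
                        strong_threshold = 6) {
  f1 <- fit_mle(perf_errors, est_errors, 1, sigma_bounds = sigma_bounds)
  f2 <- fit_mle(perf_errors, est_errors, 2, sigma_bounds = sigma_bounds,
                shift_bounds = shift_bounds)
  list(fit1 = f1, fit2 = f2,
       choice = select_model(f1, f2, strong_threshold))
}

#' Fit every subject in a preprocessed trial table
#'
#' @param trials Preprocessed trial table (no skipped rows).
#' @param ... Passed to [fit_subject()].
#' @return A data frame, one row per subject, with both models' BICs and the
#'   selected model's parameters (`sigma_prior`, `sigma_evidence`,
#'   `shift_evidence`, `w`), plus `winner`, `delta_bic`, `strong`,
#'   `boundary`, `converged`.
#' @export
fit_cohort <- function(trials, ...) {
  ids <- unique(trials$subject_id)
  rows <- lapply(ids, function(id) {
    sub <- trials[trials$subject_id == id, , drop = FALSE]
    err <- compute_errors(sub)
    fs <- tryCatch(
      fit_subject(err$performance_error, err$estimation_error, ...),
      error = function(e) stop_param("fit failed for subject ", id, ": ",
                                     conditionMessage(e)))
    sel <- if (fs$choice$winner == 2L) fs$fit2 else fs$fit1
    data.frame(subject_id = id, group = sub$group[1],
               n_trials = sel$n_trials,
               bic1 = fs$fit1$bic, bic2 = fs$fit2$bic,
               loglik1 = fs$fit1$loglik, loglik2 = fs$fit2$loglik,
               winner = fs$choice$winner, delta_bic = fs$choice$delta_bic,
               strong = fs$choice$strong,
               sigma_prior = sel$params$sigma_prior,
               sigma_evidence = sel$params$sigma_evidence,
               shift_evidence = sel$params$shift_evidence,
               w = sel$params$w,
               boundary = fs$fit1$boundary || fs$fit2$boundary,
               converged = fs$fit1$converged && fs$fit2$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
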
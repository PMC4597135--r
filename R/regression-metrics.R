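#' Per-subject regression of estimation on performance errors
#'
#' Ordinary least squares of estimation error on performance error. Under
#' the cue-integration observer the population slope equals `-w` (the
#' negative integration weight) and the intercept equals
#' `(1 - w) * shift`, so the fit summarises a subject's bias toward the
#' target in one number.
#'
#' @param perf_errors,est_errors Numeric vectors, one element per retained
#'   trial.
#' @param subject_id Optional id used in error messages.
#' @return A list with `slope`, `intercept`, `resid_sd_ml` (the
#'   maximum-likelihood residual SD, denominator `n`), and `r` (Pearson
#'   correlation).
#' @examples
#' fit_subject_regression(c(-1, 1), c(1, -1))  # slope -1, intercept 0
#' @export
fit_subject_regression <- function(perf_errors, est_errors,
                                   subject_id = NULL) {
  n <- length(perf_errors)
  if (n < 3L) {
    stop_param("subject ", subject_id %||% "", ": need >= 3 trials, got ", n)
  }
  if (length(est_errors) != n) stop_param("error vectors differ in length")
  if (var(perf_errors) == 0) {
    stop_param("subject ", subject_id %||% "",
               ": performance errors are all identical; regression undefined")
  }
  fit <- lm.fit(cbind(1, perf_errors), est_errors)
  rss <- sum(fit$residuals^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       resid_sd_ml = sqrt(rss / n),
       r = cor(perf_errors, est_errors))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample SD of performance errors
#'
#' Sample standard deviation (denominator `n - 1`), the descriptive
#' convention used throughout; the maximum-likelihood `n` denominator
#' appears only inside the likelihood.
#'
#' @param perf_errors Numeric vector of at least 2 trials.
#' @return SD in pixels.
#' @export
performance_sd <- function(perf_errors) {
  if (length(perf_errors) < 2L) stop_param("need >= 2 trials for an SD")
  sd(perf_errors)
}

#' Normalized prior width
#'
#' Scales a fitted prior SD against the subject's own performance-error SD
#' into the open unit interval. The statistic is 0.5 exactly when the prior
#' matches the true performance distribution; values below 0.5 indicate an
#' optimistically narrow prior, values above 0.5 an over-wide one.
#'
#' Two variants satisfy these constraints: the SD ratio
#' `sigma_p / (sigma_p + s_perf)` (default) and the variance ratio
#' `sigma_p^2 / (sigma_p^2 + s_perf^2)`. Both are strictly increasing in the
#' prior SD with limits 0 and 1.
#'
#' @param sigma_prior_hat Fitted prior SD (px, > 0).
#' @param perf_sd Sample SD of performance errors (px, > 0).
#' @param variant `"sd"` (default) or `"variance"`.
#' @return A value in (0, 1).
#' @examples
#' normalized_prior(10, 10)  # 0.5: prior matches performance
#' normalized_prior(30, 10)  # 0.75: prior wider than performance
#' @export
normalized_prior <- function(sigma_prior_hat, perf_sd,
                             variant = c("sd", "variance")) {
  variant <- match.arg(variant)
  if (any(sigma_prior_hat <= 0) || any(perf_sd <= 0)) {
    stop_param("normalized_prior() needs strictly positive inputs")
  }
  if (variant == "sd") {
    sigma_prior_hat / (sigma_prior_hat + perf_sd)
  } else {
    sigma_prior_hat^2 / (sigma_prior_hat^2 + perf_sd^2)
  }
}

#' Prior accuracy
#'
#' Absolute deviation of the normalized prior from 0.5. Zero means the prior
#' width matches the subject's true performance distribution exactly;
#' larger values mean a prior further from it (in either direction).
#'
#' @param np Normalized prior value(s) in (0, 1).
#' @return Value(s) in `[0, 0.5]`.
#' @export
prior_accuracy <- function(np) {
  if (any(np <= 0) || any(np >= 1)) {
    stop_param("normalized prior must lie in (0, 1)")
  }
  abs(np - 0.5)
}

#' Per-subject derived measures
#'
#' Combines preprocessed trials and model fits into one row per subject:
#' performance statistics, the estimation-vs-performance regression, mean
#' estimation time, and the prior metrics computed from the selected model's
#' fitted prior SD.
#'
#' @param trials Preprocessed trial table (skips and exclusions applied).
#' @param fits Per-subject fit table from [fit_cohort()] (one row per
#'   subject, columns include `sigma_prior`, `sigma_evidence`,
#'   `shift_evidence`, `winner`, `boundary`).
#' @param covariates Optional data frame with `subject_id` plus covariate
#'   columns (e.g. `lde`) merged in.
#' @param variant Normalization variant, see [normalized_prior()].
#' @return A data frame of subject measures.
#' @export
compute_subject_measures <- function(trials, fits, covariates = NULL,
                                     variant = c("sd", "variance")) {
  variant <- match.arg(variant)
  ids <- unique(trials$subject_id)
  rows <- lapply(ids, function(id) {
    sub <- trials[trials$subject_id == id, , drop = FALSE]
    err <- compute_errors(sub)
    reg <- fit_subject_regression(err$performance_error,
                                  err$estimation_error, subject_id = id)
    psd <- performance_sd(err$performance_error)
    f <- fits[fits$subject_id == id, , drop = FALSE]
    if (nrow(f) != 1L) stop_param("no unique fit row for subject ", id)
    np <- normalized_prior(f$sigma_prior, psd, variant = variant)
    data.frame(subject_id = id, group = sub$group[1],
               n_trials = nrow(sub),
               perf_sd = psd, perf_mean = mean(err$performance_error),
               slope = reg$slope, intercept = reg$intercept,
               resid_sd_ml = reg$resid_sd_ml,
               mean_est_time = mean(sub$estimation_time),
               sigma_prior = f$sigma_prior,
               sigma_evidence = f$sigma_evidence,
               shift_evidence = f$shift_evidence,
               winner = f$winner, boundary = f$boundary,
               normalized_prior = np,
               prior_accuracy = prior_accuracy(np),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(covariates)) {
    out <- merge(out, covariates, by = "subject_id", all.x = TRUE,
                 sort = FALSE)
  }
  rownames(out) <- NULL
  out
}
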
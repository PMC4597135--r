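#' Screen geometry for the Stop task
#'
#' The task display: a touch screen on which a ball sweeps horizontally and
#' the target sits at the horizontal centre. Positions throughout the package
#' are absolute screen pixels; analyses re-centre on the target internally.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param px_per_cm Pixel density (pixels per centimetre).
#' @return A list with class `"screen_geometry"`; `target_x` is the
#'   horizontal centre.
#' @export
screen_geometry <- function(width_px = 1024, height_px = 768, px_per_cm = 26) {
  check_positive(width_px, "width_px")
  check_positive(height_px, "height_px")
  check_positive(px_per_cm, "px_per_cm")
  structure(list(width_px = width_px, height_px = height_px,
                 px_per_cm = px_per_cm, target_x = width_px / 2),
            class = "screen_geometry")
}

#' Ground-truth generative parameters for one simulated subject
#'
#' Describes how a subject produces trials: how their stopping positions
#' scatter around the target (motor performance), and how they perceive the
#' outcome — a Gaussian prior of width `sigma_prior` centred on the target
#' integrated with Gaussian sensory evidence of width `sigma_evidence`
#' centred on the true stopping position plus a constant spatial shift
#' (leftward negative, attributed to the left-hand pointing procedure).
#'
#' The implied integration weight is
#' `w = sigma_evidence^2 / (sigma_prior^2 + sigma_evidence^2)`; the perceived
#' position is `w * target + (1 - w) * (evidence + shift)`.
#'
#' @param subject_id Character id.
#' @param group `"patient"` or `"control"`.
#' @param sigma_performance SD (px) of stopping position about the target.
#' @param mu_performance Mean signed stopping offset (px, rightward
#'   positive). Default -10 px, a small leftward bias.
#' @param sigma_prior Prior SD (px) over outcomes, centred on the target.
#' @param sigma_evidence Sensory evidence SD (px).
#' @param shift_evidence Constant signed shift (px) on the evidence;
#'   default -20 (leftward).
#' @param skip_prob Per-trial probability of skipping the estimate, in
#'   `[0, 1)`.
#' @param est_time_median Median estimation time in seconds (log-normal);
#'   defaults to 1.07 s for patients and 0.88 s for controls.
#' @param est_time_sigma_log Log-normal shape (sdlog) of estimation times.
#' @param lde Levodopa dose equivalent (mg/day) or `NA` for controls.
#' @return A list with class `"subject_params"`, including the implied
#'   weight `w`.
#' @export
subject_params <- function(subject_id,
                           group = c("patient", "control"),
                           sigma_performance = 40,
                           mu_performance = -10,
                           sigma_prior = 25,
                           sigma_evidence = 30,
                           shift_evidence = -20,
                           skip_prob = 0.04,
                           est_time_median = NULL,
                           est_time_sigma_log = 0.3,
                           lde = NA_real_) {
  group <- match.arg(group)
  check_positive(sigma_performance, "sigma_performance")
  check_positive(sigma_prior, "sigma_prior")
  check_positive(sigma_evidence, "sigma_evidence")
  if (!is.numeric(skip_prob) || skip_prob < 0 || skip_prob >= 1) {
    stop_param("`skip_prob` must lie in [0, 1)")
  }
  if (is.null(est_time_median)) {
    est_time_median <- if (group == "patient") 1.07 else 0.88
  }
  check_positive(est_time_median, "est_time_median")
  if (est_time_sigma_log < 0) stop_param("`est_time_sigma_log` must be >= 0")
  if (!is.na(lde) && lde < 0) stop_param("`lde` must be >= 0 or NA")
  w <- sigma_evidence^2 / (sigma_prior^2 + sigma_evidence^2)
  stopifnot(w > 0, w < 1)
  structure(list(subject_id = as.character(subject_id), group = group,
                 sigma_performance = sigma_performance,
                 mu_performance = mu_performance,
                 sigma_prior = sigma_prior,
                 sigma_evidence = sigma_evidence,
                 shift_evidence = shift_evidence,
                 skip_prob = skip_prob,
                 est_time_median = est_time_median,
                 est_time_sigma_log = est_time_sigma_log,
                 lde = lde, w = w),
            class = "subject_params")
}

# Draw the raw per-trial quantities for n trials. Sweep labels and stopping
# times are decorative: no analysis consumes them.
draw_trials <- function(params, n, geometry) {
  w <- params$w
  target_x <- geometry$target_x
  p <- rnorm(n, params$mu_performance, params$sigma_performance)
  e <- rnorm(n, p + params$shift_evidence, params$sigma_evidence)
  skipped <- runif(n) < params$skip_prob
  n_sweeps <- sample(1:3, n, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  stop_time <- (n_sweeps - 1) * 1.3 + runif(n, 0.1, 1.3)
  est_time <- rlnorm(n, meanlog = log(params$est_time_median),
                     sdlog = params$est_time_sigma_log)
  point_x <- target_x + (1 - w) * e
  point_x[skipped] <- NA_real_
  est_time[skipped] <- NA_real_
  data.frame(subject_id = params$subject_id, group = params$group,
             block = 1L, trial_index = seq_len(n),
             target_x = target_x, stop_x = target_x + p,
             point_x = point_x, stop_time = stop_time,
             estimation_time = est_time, skipped = skipped,
             n_sweeps = n_sweeps, stringsAsFactors = FALSE)
}

#' Simulate the Stop task for one subject
#'
#' Generates one trial table from ground-truth observer parameters. On each
#' non-skipped trial the stopping position is drawn about the target, noisy
#' evidence is drawn about the stopping position (plus the constant shift),
#' and the reported position is the precision-weighted combination of target
#' (prior mean) and evidence. Skipped trials carry no pointing position or
#' estimation time.
#'
#' @param params A [subject_params()] object.
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param geometry A [screen_geometry()].
#' @param blocks Number of blocks the trials are labelled into.
#' @param replace_skipped If `TRUE`, extra trials are appended until
#'   `n_trials` non-skipped trials exist (the task's "additional trial added
#'   instead" policy); the returned table then has more than `n_trials` rows.
#' @return A data frame, one row per trial, with columns `subject_id`,
#'   `group`, `block`, `trial_index`, `target_x`, `stop_x`, `point_x`,
#'   `stop_time`, `estimation_time`, `skipped`, `n_sweeps`.
#' @examples
#' p <- subject_params("s1", "control", sigma_prior = 20, sigma_evidence = 20)
#' trials <- simulate_subject(p, n_trials = 104, seed = 1)
#' @export
simulate_subject <- function(params, n_trials, seed,
                             geometry = screen_geometry(),
                             blocks = 2, replace_skipped = FALSE) {
  if (!inherits(params, "subject_params")) {
    stop_param("`params` must be created with subject_params()")
  }
  if (!is.numeric(n_trials) || n_trials < 1) {
    stop_param("`n_trials` must be >= 1")
  }
  n_trials <- as.integer(n_trials)
  with_seed(seed, {
    trials <- draw_trials(params, n_trials, geometry)
    if (replace_skipped) {
      # top up until the non-skipped count reaches n_trials
      while (sum(!trials$skipped) < n_trials) {
        extra <- draw_trials(params, sum(trials$skipped) -
                               (nrow(trials) - n_trials), geometry)
        trials <- rbind(trials, extra)
      }
      trials$trial_index <- seq_len(nrow(trials))
    }
    per_block <- ceiling(nrow(trials) / blocks)
    trials$block <- pmin(blocks, (trials$trial_index - 1L) %/% per_block + 1L)
    trials
  })
}

#' Cohort specification for simulation
#'
#' Describes a two-group study: per-group sample sizes, the trial schedule
#' (blocks x trials per block), and the distributions the per-subject
#' generative parameters are drawn from. Each `*_range` is sampled uniformly;
#' `param_jitter` scales all ranges about their midpoint, so
#' `param_jitter = 0` makes every subject in a group identical.
#'
#' Defaults mirror the study design this package emulates: 20 patients and
#' 20 controls, 2 blocks of 52 trials, ~4% skipped trials, estimation-time
#' medians of 1.07 s (patients) and 0.88 s (controls), and an optimistic
#' prior narrower than the performance distribution.
#'
#' @param n_patients,n_controls Subjects per group.
#' @param blocks,trials_per_block Trial schedule (total 104 by default).
#' @param sigma_performance_range Per-group list of uniform ranges (px).
#' @param sigma_prior_ratio_range Range of `sigma_prior / sigma_performance`;
#'   below 1 means optimistic (narrow) priors.
#' @param sigma_evidence_range Uniform range for evidence SD (px).
#' @param shift_mean,shift_sd Normal distribution of the evidence shift (px).
#' @param mu_performance Mean stopping offset (px).
#' @param skip_prob Per-trial skip probability.
#' @param est_time_median Per-group named list of median estimation times (s).
#' @param est_time_sigma_log Log-normal shape of estimation times.
#' @param lde_range Uniform range of levodopa dose equivalents (mg/day),
#'   patients only.
#' @param lde_link If `TRUE`, patients' prior widths increase monotonically
#'   with LDE (wider, i.e. less optimistic, priors at higher doses), with
#'   multiplicative log-normal jitter `lde_link_jitter`; this overrides
#'   `sigma_prior_ratio_range` for patients.
#' @param lde_link_jitter sdlog of the jitter on the LDE -> prior-width map.
#' @param param_jitter Scale in `[0, 1]` applied to all sampling ranges.
#' @param replace_skipped Passed to [simulate_subject()].
#' @return A list with class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_patients = 20, n_controls = 20,
                        blocks = 2, trials_per_block = 52,
                        sigma_performance_range =
                          list(patient = c(35, 65), control = c(25, 50)),
                        sigma_prior_ratio_range = c(0.45, 0.85),
                        sigma_evidence_range = c(18, 40),
                        shift_mean = -20, shift_sd = 8,
                        mu_performance = -10,
                        skip_prob = 0.04,
                        est_time_median = list(patient = 1.07, control = 0.88),
                        est_time_sigma_log = 0.3,
                        lde_range = c(200, 1800),
                        lde_link = FALSE,
                        lde_link_jitter = 0.12,
                        param_jitter = 1,
                        replace_skipped = FALSE) {
  if (n_patients < 1 && n_controls < 1) {
    stop_param("at least one group must be non-empty")
  }
  if (param_jitter < 0 || param_jitter > 1) {
    stop_param("`param_jitter` must lie in [0, 1]")
  }
  structure(as.list(environment()), class = "cohort_spec")
}

# uniform draw from rng, shrunk about its midpoint by the jitter scale
runif_jittered <- function(n, rng, jitter) {
  mid <- mean(rng)
  mid + (runif(n) - 0.5) * diff(rng) * jitter
}

#' Simulate a full two-group cohort
#'
#' Draws per-subject generative parameters from a [cohort_spec()], then
#' simulates each subject's trial table. The ground truth is retained so
#' parameter-recovery checks can compare fitted against generating values.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; fixes parameter draws and every trial stream.
#' @param geometry A [screen_geometry()].
#' @return A list with `trials` (row-bound trial tables) and `truth` (one row
#'   per subject: all generative parameters plus the implied weight `w`).
#' @examples
#' demo <- simulate_cohort(cohort_spec(n_patients = 3, n_controls = 3), seed = 7)
#' table(demo$trials$group)
#' @export
simulate_cohort <- function(spec, seed, geometry = screen_geometry()) {
  if (!inherits(spec, "cohort_spec")) {
    stop_param("`spec` must be created with cohort_spec()")
  }
  n_trials <- spec$blocks * spec$trials_per_block
  groups <- c(rep("patient", spec$n_patients), rep("control", spec$n_controls))
  ids <- c(sprintf("P%02d", seq_len(spec$n_patients)),
           sprintf("C%02d", seq_len(spec$n_controls)))
  params <- with_seed(seed, {
    jit <- spec$param_jitter
    lapply(seq_along(ids), function(i) {
      g <- groups[i]
      sig_perf <- runif_jittered(1, spec$sigma_performance_range[[g]], jit)
      sig_ev <- runif_jittered(1, spec$sigma_evidence_range, jit)
      shift <- spec$shift_mean + rnorm(1) * spec$shift_sd * jit
      lde <- NA_real_
      if (g == "patient") {
        lde <- runif_jittered(1, spec$lde_range, jit)
      }
      if (spec$lde_link && g == "patient") {
        # monotone map: higher LDE -> wider (less optimistic) prior
        frac <- (lde - spec$lde_range[1]) / diff(spec$lde_range)
        ratio <- (0.35 + 0.75 * frac) *
          exp(rnorm(1, 0, spec$lde_link_jitter * jit))
      } else {
        ratio <- runif_jittered(1, spec$sigma_prior_ratio_range, jit)
      }
      subject_params(ids[i], g,
                     sigma_performance = sig_perf,
                     mu_performance = spec$mu_performance,
                     sigma_prior = ratio * sig_perf,
                     sigma_evidence = sig_ev,
                     shift_evidence = shift,
                     skip_prob = spec$skip_prob,
                     est_time_median = spec$est_time_median[[g]],
                     est_time_sigma_log = spec$est_time_sigma_log,
                     lde = lde)
    })
  })
  trial_seeds <- with_seed(seed + 1L, sample.int(.Machine$integer.max - 1L,
                                                 length(ids)))
  trials <- do.call(rbind, lapply(seq_along(params), function(i) {
    simulate_subject(params[[i]], n_trials, seed = trial_seeds[i],
                     geometry = geometry, blocks = spec$blocks,
                     replace_skipped = spec$replace_skipped)
  }))
  truth <- do.call(rbind, lapply(params, function(p) {
    data.frame(subject_id = p$subject_id, group = p$group,
               sigma_performance = p$sigma_performance,
               mu_performance = p$mu_performance,
               sigma_prior = p$sigma_prior,
               sigma_evidence = p$sigma_evidence,
               shift_evidence = p$shift_evidence,
               skip_prob = p$skip_prob,
               est_time_median = p$est_time_median,
               est_time_sigma_log = p$est_time_sigma_log,
               lde = p$lde, w = p$w, stringsAsFactors = FALSE)
  }))
  rownames(trials) <- rownames(truth) <- NULL
  list(trials = trials, truth = truth)
}
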
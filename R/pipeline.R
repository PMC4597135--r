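#' Pipeline configuration
#'
#' All tunables of the end-to-end analysis in one validated object. Defaults
#' reproduce the study conventions: 1024 x 768 screen at 26 px/cm, 2 blocks
#' of 52 trials, one-sided 2-SD slow-trial rule, one-sided 3-SD
#' outlier-subject rule, SD-ratio prior normalization, BIC strong-evidence
#' threshold 6, and boundary-flagged fits excluded from prior correlations.
#'
#' @param geometry A [screen_geometry()].
#' @param blocks,trials_per_block,practice_trials Trial schedule.
#' @param slow_n_sd,slow_sided Slow-trial exclusion rule.
#' @param subject_n_sd Outlier-subject exclusion rule.
#' @param normalization `"sd"` or `"variance"`, see [normalized_prior()].
#' @param sigma_bounds,shift_bounds MLE parameter bounds (px).
#' @param strong_threshold BIC difference labelled strong evidence.
#' @param exclude_boundary Exclude boundary-flagged subjects from the
#'   normalized-prior correlation analyses.
#' @return A list with class `"pipeline_config"`.
#' @export
pipeline_config <- function(geometry = screen_geometry(),
                            blocks = 2, trials_per_block = 52,
                            practice_trials = 12,
                            slow_n_sd = 2, slow_sided = "upper",
                            subject_n_sd = 3,
                            normalization = c("sd", "variance"),
                            sigma_bounds = c(1e-3, 1e4),
                            shift_bounds = c(-5e3, 5e3),
                            strong_threshold = 6,
                            exclude_boundary = TRUE) {
  normalization <- match.arg(normalization)
  stopifnot(blocks >= 1, trials_per_block >= 1, practice_trials >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_param("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' preprocess -> per-subject model fits -> derived measures -> group
#' statistics. Input is either a trial table (e.g. from [read_trials()]) or
#' a [cohort_spec()] to simulate from; deterministic given `seed`.
#'
#' The statistics mirror the study's analysis plan: group comparison of
#' estimation times; per-group and between-group tests on regression slopes;
#' group comparisons of performance SD, evidence SD and evidence shift; a
#' sign test on how many subjects the 3-parameter model wins by BIC;
#' one-sample tests of the normalized prior against 0.5 per group; an
#' ANCOVA of the normalized prior on group with mean estimation time as
#' nuisance covariate; and, when an `lde` covariate is available, Spearman
#' and partial Spearman correlations of normalized prior / prior accuracy /
#' evidence SD with LDE.
#'
#' @param trials A trial table, or `NULL` to simulate.
#' @param cohort A [cohort_spec()] used when `trials` is `NULL`.
#' @param covariates Optional per-subject covariate data frame
#'   (`subject_id`, `lde`, ...); when simulating, the ground-truth LDE is
#'   used automatically.
#' @param config A [pipeline_config()].
#' @param seed Integer seed (simulation only; the analysis itself is
#'   deterministic).
#' @return A bundle list: `trials` (clean), `exclusions`, `fits`,
#'   `measures`, `stats` (named [stat_result()]s), `truth` (simulation
#'   only), `provenance`.
#' @export
run_pipeline <- function(trials = NULL, cohort = NULL, covariates = NULL,
                         config = pipeline_config(), seed = 1L) {
  if (is.null(trials)) {
    cohort <- cohort %||% cohort_spec()
    sim <- stage("simulate", simulate_cohort(cohort, seed = seed,
                                             geometry = config$geometry))
    trials <- sim$trials
    truth <- sim$truth
    if (is.null(covariates)) {
      covariates <- truth[, c("subject_id", "lde")]
    }
  } else {
    truth <- NULL
    stage("validate", validate_trials(trials))
  }
  pre <- stage("preprocess",
               preprocess_trials(trials, slow_n_sd = config$slow_n_sd,
                                 slow_sided = config$slow_sided,
                                 subject_n_sd = config$subject_n_sd))
  fits <- stage("fit",
                fit_cohort(pre$trials, sigma_bounds = config$sigma_bounds,
                           shift_bounds = config$shift_bounds,
                           strong_threshold = config$strong_threshold))
  measures <- stage("metrics",
                    compute_subject_measures(pre$trials, fits,
                                             covariates = covariates,
                                             variant = config$normalization))
  stats <- stage("analyze", pipeline_stats(measures, fits, config))
  provenance <- list(package = "selfprior",
                     version = as.character(utils::packageVersion("selfprior")),
                     r_version = R.version.string,
                     seed = seed,
                     config = unclass(config)[setdiff(names(config),
                                                      "geometry")],
                     geometry = unclass(config$geometry),
                     n_subjects_in = length(unique(trials$subject_id)),
                     n_subjects_retained = nrow(measures))
  list(trials = pre$trials, exclusions = pre$report, fits = fits,
       measures = measures, stats = stats, truth = truth,
       provenance = provenance)
}

pipeline_stats <- function(measures, fits, config) {
  pat <- measures[measures$group == "patient", , drop = FALSE]
  ctl <- measures[measures$group == "control", , drop = FALSE]
  two_groups <- nrow(pat) >= 2 && nrow(ctl) >= 2
  stats <- list()
  if (two_groups) {
    stats$est_time_group <- t_test_stat(pat$mean_est_time, ctl$mean_est_time,
                                        test_name = "estimation time: patients vs controls")
    stats$slope_group <- t_test_stat(pat$slope, ctl$slope,
                                     test_name = "regression slope: patients vs controls")
    stats$perf_sd_group <- t_test_stat(pat$perf_sd, ctl$perf_sd,
                                       test_name = "performance SD: patients vs controls")
    stats$sigma_evidence_group <- t_test_stat(pat$sigma_evidence,
                                              ctl$sigma_evidence,
                                              test_name = "evidence SD: patients vs controls")
    stats$shift_group <- t_test_stat(pat$shift_evidence, ctl$shift_evidence,
                                     test_name = "evidence shift: patients vs controls")
    stats$shift_vs_zero <- t_test_stat(measures$shift_evidence, mu = 0,
                                       test_name = "evidence shift vs 0 (all subjects)")
  }
  if (nrow(pat) >= 2) {
    stats$slope_patients <- t_test_stat(pat$slope, mu = 0,
                                        test_name = "slope < 0: patients")
    stats$np_patients <- t_test_stat(pat$normalized_prior, mu = 0.5,
                                     test_name = "normalized prior vs 0.5: patients")
  }
  if (nrow(ctl) >= 2) {
    stats$slope_controls <- t_test_stat(ctl$slope, mu = 0,
                                        test_name = "slope < 0: controls")
    stats$np_controls <- t_test_stat(ctl$normalized_prior, mu = 0.5,
                                     test_name = "normalized prior vs 0.5: controls")
  }
  stats$model2_sign_test <- sign_test_exact(sum(fits$winner == 2L),
                                            nrow(fits))
  if (two_groups && nrow(pat) >= 3 && nrow(ctl) >= 3) {
    stats <- c(stats, setNames(
      ancova_type3(measures$normalized_prior, measures$group,
                   measures$mean_est_time),
      c("ancova_group", "ancova_est_time", "ancova_interaction")))
  }
  # prior correlations use patients with clean (non-boundary) fits
  cp <- pat
  if (config$exclude_boundary) cp <- cp[!cp$boundary, , drop = FALSE]
  if ("lde" %in% names(cp) && sum(!is.na(cp$lde)) >= 5) {
    cp <- cp[!is.na(cp$lde), , drop = FALSE]
    stats$np_lde <- spearman_test(cp$normalized_prior, cp$lde,
                                  test_name = "normalized prior vs LDE (patients)")
    stats$accuracy_lde <- spearman_test(cp$prior_accuracy, cp$lde,
                                        test_name = "prior accuracy vs LDE (patients)")
    stats$sigma_prior_lde <- spearman_test(cp$sigma_prior, cp$lde,
                                           test_name = "prior SD vs LDE (patients)")
    stats$sigma_evidence_lde <- spearman_test(cp$sigma_evidence, cp$lde,
                                              test_name = "evidence SD vs LDE (patients)")
    stats$np_lde_partial_est_time <-
      partial_spearman(cp$normalized_prior, cp$lde, cp$mean_est_time,
                       test_name = "normalized prior vs LDE | estimation time")
  }
  stats
}

#' Human-readable report of a pipeline bundle
#'
#' Markdown summary: exclusions, a per-subject table (slope, fitted SDs,
#' shift, BIC winner, normalized prior and accuracy) and every group
#' statistic. Regenerating the report from the same bundle is byte
#' identical.
#'
#' @param bundle A bundle from [run_pipeline()].
#' @return A character vector of lines, invisibly printable via `cat`.
#' @export
report_bundle <- function(bundle) {
  m <- bundle$measures
  lines <- c("# Stop-task observer analysis", "",
             sprintf("Subjects retained: %d (of %d)", nrow(m),
                     bundle$provenance$n_subjects_in), "")
  excl <- bundle$exclusions
  if (any(excl$subject_excluded)) {
    lines <- c(lines, "## Excluded subjects", "",
               sprintf("- %s: %s",
                       excl$subject_id[excl$subject_excluded],
                       excl$reason[excl$subject_excluded]), "")
  }
  lines <- c(lines, "## Per-subject measures", "",
             paste("subject | group | slope | sigma_prior | sigma_evidence |",
                   "shift | model | normalized_prior | accuracy"),
             "---|---|---|---|---|---|---|---|---",
             sprintf("%s | %s | %.3f | %.1f | %.1f | %.1f | %d | %.3f | %.3f",
                     m$subject_id, m$group, m$slope, m$sigma_prior,
                     m$sigma_evidence, m$shift_evidence, m$winner,
                     m$normalized_prior, m$prior_accuracy),
             "", "## Group statistics", "")
  for (s in bundle$stats) {
    lines <- c(lines, sprintf(
      "- %s: statistic = %.4g, df = %s, p = %.4g%s", s$test_name,
      s$statistic, paste(format(s$df, digits = 4), collapse = ","),
      s$p_value,
      if (!is.na(s$effect_size)) sprintf(", effect = %.4g", s$effect_size)
      else ""))
  }
  lines
}
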
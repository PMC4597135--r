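#' Signed error pair for each trial
#'
#' Performance error is where the ball actually stopped relative to the
#' target; estimation error is where the subject pointed relative to where
#' the ball actually stopped. Both are signed, rightward positive.
#'
#' @param trials A trial table (see [simulate_subject()] for the schema).
#'   Must contain no skipped rows.
#' @return A data frame with columns `performance_error` and
#'   `estimation_error` (px), one row per trial.
#' @examples
#' compute_errors(data.frame(target_x = 512, stop_x = 520, point_x = 515,
#'                           skipped = FALSE))  # (8, -5)
#' @export
compute_errors <- function(trials) {
  if (!all(c("target_x", "stop_x", "point_x") %in% names(trials))) {
    stop_param("trial table must have target_x, stop_x, point_x")
  }
  if (("skipped" %in% names(trials)) && any(trials$skipped)) {
    stop_param("compute_errors() on skipped trials: drop them first ",
               "(drop_skipped())")
  }
  data.frame(performance_error = trials$stop_x - trials$target_x,
             estimation_error = trials$point_x - trials$stop_x)
}

#' Remove skipped trials
#'
#' Skipped trials carry no estimate and are excluded outright; row order is
#' preserved. Warns if nothing remains.
#'
#' @param trials A trial table with a logical `skipped` column.
#' @return The table without skipped rows.
#' @export
drop_skipped <- function(trials) {
  if (!"skipped" %in% names(trials)) stop_param("no `skipped` column")
  out <- trials[!trials$skipped, , drop = FALSE]
  if (nrow(out) == 0L && nrow(trials) > 0L) {
    warning("all trials skipped; empty table returned", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Exclude slow estimation trials for one subject
#'
#' Removes trials whose estimation time exceeds the subject's mean plus
#' `n_sd` sample SDs. The rule is one-sided (long estimation times indicate
#' interference from memory processes; fast ones do not), uses a single pass
#' (mean and SD include the candidate outliers) and a strict inequality at
#' the threshold. A two-sided variant is available via `sided`.
#'
#' @param trials Trial table for one subject, skipped rows already dropped.
#' @param n_sd Number of SDs defining the threshold (default 2).
#' @param sided `"upper"` (default) or `"two"`.
#' @return A list with `trials` (retained rows) and `n_excluded`.
#' @export
exclude_slow_trials <- function(trials, n_sd = 2, sided = c("upper", "two")) {
  sided <- match.arg(sided)
  if (length(unique(trials$subject_id)) > 1L) {
    stop_param("exclude_slow_trials() works on one subject at a time")
  }
  if (nrow(trials) < 2L) {
    warning("fewer than 2 trials; no exclusion applied", call. = FALSE)
    return(list(trials = trials, n_excluded = 0L))
  }
  t_est <- trials$estimation_time
  m <- mean(t_est)
  s <- sd(t_est)
  slow <- t_est > m + n_sd * s
  if (sided == "two") slow <- slow | (t_est < m - n_sd * s)
  out <- trials[!slow, , drop = FALSE]
  rownames(out) <- NULL
  list(trials = out, n_excluded = sum(slow))
}

#' Exclude outlier subjects on mean estimation time
#'
#' Within each group separately, flags subjects whose mean estimation time
#' exceeds the group mean plus `n_sd` group SDs (single pass, one-sided
#' upper, strict inequality). Groups with fewer than 3 subjects are left
#' untouched with a warning.
#'
#' @param mean_est_time Numeric vector of per-subject mean estimation times.
#' @param group Character/factor vector of group labels, same length.
#' @param subject_id Subject ids, same length (defaults to names of
#'   `mean_est_time`).
#' @param n_sd Number of SDs defining the threshold (default 3).
#' @return Character vector of excluded subject ids (possibly empty).
#' @export
exclude_outlier_subjects <- function(mean_est_time, group,
                                     subject_id = names(mean_est_time),
                                     n_sd = 3) {
  if (is.null(subject_id)) stop_param("subject ids required")
  if (length(mean_est_time) != length(group) ||
      length(group) != length(subject_id)) {
    stop_param("mean_est_time, group, subject_id must have equal length")
  }
  excluded <- character(0)
  for (g in unique(group)) {
    idx <- group == g
    if (sum(idx) < 3L) {
      warning("group '", g, "' has fewer than 3 subjects; no exclusion",
              call. = FALSE)
      next
    }
    m <- mean(mean_est_time[idx])
    s <- sd(mean_est_time[idx])
    out <- idx & (mean_est_time > m + n_sd * s)
    excluded <- c(excluded, as.character(subject_id[out]))
  }
  excluded
}

#' Full preprocessing of a trial table
#'
#' Applies the exclusion cascade in order: drop skipped trials, exclude slow
#' estimation trials per subject (2 SD rule), then exclude whole subjects
#' whose mean estimation time (computed from retained trials) is an outlier
#' within their group (3 SD rule).
#'
#' @param trials A trial table covering one or more subjects.
#' @param slow_n_sd,slow_sided Passed to [exclude_slow_trials()].
#' @param subject_n_sd Passed to [exclude_outlier_subjects()].
#' @return A list with `trials` (retained rows), `report` (one row per input
#'   subject: `subject_id`, `n_trials_in`, `n_skipped`, `n_slow_excluded`,
#'   `subject_excluded`, `reason`) and `excluded_subjects`.
#' @export
preprocess_trials <- function(trials, slow_n_sd = 2,
                              slow_sided = c("upper", "two"),
                              subject_n_sd = 3) {
  slow_sided <- match.arg(slow_sided)
  if (nrow(trials) == 0L) stop_param("empty trial table")
  ids <- unique(trials$subject_id)
  kept <- list()
  report <- lapply(ids, function(id) {
    sub <- trials[trials$subject_id == id, , drop = FALSE]
    n_in <- nrow(sub)
    sub <- drop_skipped(sub)
    n_skip <- n_in - nrow(sub)
    res <- exclude_slow_trials(sub, n_sd = slow_n_sd, sided = slow_sided)
    kept[[id]] <<- res$trials
    data.frame(subject_id = id, n_trials_in = n_in, n_skipped = n_skip,
               n_slow_excluded = res$n_excluded, subject_excluded = FALSE,
               reason = "", stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, report)
  mean_times <- vapply(kept, function(x) mean(x$estimation_time), numeric(1))
  groups <- vapply(kept, function(x) x$group[1], character(1))
  excl <- exclude_outlier_subjects(mean_times, groups,
                                   subject_id = names(kept),
                                   n_sd = subject_n_sd)
  report$subject_excluded <- report$subject_id %in% excl
  report$reason[report$subject_excluded] <-
    sprintf("mean estimation time > group mean + %g SD", subject_n_sd)
  out <- do.call(rbind, kept[setdiff(names(kept), excl)])
  rownames(out) <- NULL
  list(trials = out, report = report, excluded_subjects = excl)
}
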
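trial_columns <- c("subject_id", "group", "block", "trial_index",
                   "target_x", "stop_x", "point_x", "stop_time",
                   "estimation_time", "skipped", "n_sweeps")
numeric_trial_columns <- c("block", "trial_index", "target_x", "stop_x",
                           "point_x", "stop_time", "estimation_time",
                           "n_sweeps")

#' Read a trial table from CSV
#'
#' Validates the documented schema strictly: all mandatory columns present,
#' numeric columns numeric, `point_x`/`estimation_time` present on every
#' non-skipped row. Errors name the offending data row. Unknown extra
#' columns are preserved.
#'
#' @param path Path to a CSV written by [write_trials()] (UTF-8, `.`
#'   decimal).
#' @return A trial data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop_param("no such file: ", path)
  trials <- read.csv(path, stringsAsFactors = FALSE)
  validate_trials(trials, where = path)
  trials
}

validate_trials <- function(trials, where = "trial table") {
  miss <- setdiff(trial_columns, names(trials))
  if (length(miss)) {
    stop_param(where, ": missing mandatory column(s): ",
               paste(miss, collapse = ", "))
  }
  if (nrow(trials) == 0L) stop_param(where, ": empty trial table")
  if (is.character(trials$skipped)) {
    trials$skipped <- trials$skipped %in% c("true", "TRUE", "True")
  }
  if (!is.logical(trials$skipped)) {
    bad <- which(!trials$skipped %in% c(0, 1))
    if (length(bad)) {
      stop_param(where, ": non-boolean 'skipped' at row ", bad[1])
    }
  }
  for (cl in numeric_trial_columns) {
    v <- trials[[cl]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & v != "")
      if (length(bad)) {
        stop_param(where, ": non-numeric '", cl, "' at row ", bad[1])
      }
    }
  }
  optional_when_skipped <- c("point_x", "estimation_time")
  for (cl in setdiff(numeric_trial_columns, optional_when_skipped)) {
    bad <- which(is.na(trials[[cl]]))
    if (length(bad)) stop_param(where, ": missing '", cl, "' at row ", bad[1])
  }
  for (cl in optional_when_skipped) {
    bad <- which(is.na(trials[[cl]]) & !as.logical(trials$skipped))
    if (length(bad)) {
      stop_param(where, ": missing '", cl, "' on non-skipped row ", bad[1])
    }
  }
  invisible(trials)
}

#' Write a trial table to CSV
#'
#' @param trials A trial data frame (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  write.csv(trials, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

# flatten a stat_result (or list of them) for JSON output
stat_to_list <- function(x) {
  if (inherits(x, "stat_result")) return(unclass(x))
  lapply(x, stat_to_list)
}

#' Write a pipeline result bundle to disk
#'
#' @param bundle A result bundle from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `clean_trials.csv`, `exclusions.csv`,
#'   `fits.csv`, `measures.csv`, `stats.json` and `provenance.json`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trials(bundle$trials, file.path(dir, "clean_trials.csv"))
  write.csv(bundle$exclusions, file.path(dir, "exclusions.csv"),
            row.names = FALSE)
  write.csv(bundle$fits, file.path(dir, "fits.csv"), row.names = FALSE)
  write.csv(bundle$measures, file.path(dir, "measures.csv"),
            row.names = FALSE)
  jsonlite::write_json(stat_to_list(bundle$stats),
                       file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
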
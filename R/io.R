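# Plain-CSV interchange: one file per recording (time_s + six channels, task
# metadata in '#' header comments) plus a manifest.

#' Write a recording to CSV
#'
#' Columns: time_s, acc_v, acc_ml, acc_ap, gyr_yaw, gyr_pitch, gyr_roll.
#' Metadata (participant, group, task, trial, fs) goes into leading `#`
#' comment lines.
#'
#' @param rec a `sensor_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# participant_id: %s", rec$participant_id), con)
  writeLines(sprintf("# group: %s", rec$group), con)
  writeLines(sprintf("# task: %s", rec$task), con)
  writeLines(sprintf("# trial: %s", rec$trial_index), con)
  writeLines(sprintf("# fs: %g", rec$fs), con)
  df <- data.frame(
    time_s = (seq_along(rec$acc_v) - 1) / rec$fs,
    acc_v = rec$acc_v, acc_ml = rec$acc_ml, acc_ap = rec$acc_ap,
    gyr_yaw = rec$gyr_yaw, gyr_pitch = rec$gyr_pitch, gyr_roll = rec$gyr_roll)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV file path.
#' @return a `sensor_recording` (without ground-truth attributes).
#' @export
read_recording <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  tr <- meta("trial")
  new_sensor_recording(
    fs = as.numeric(meta("fs")),
    series = as.list(df[, c("acc_v", "acc_ml", "acc_ap", "gyr_yaw",
                            "gyr_pitch", "gyr_roll")]),
    task = meta("task"),
    trial_index = if (tr %in% c("NA", "")) NA_integer_ else as.integer(tr),
    participant_id = meta("participant_id"),
    group = meta("group"))
}

#' Write a cohort of recordings plus a manifest
#'
#' @param recordings list from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- attr(recordings, "manifest")
  man$path <- vapply(seq_along(recordings), function(i) {
    r <- recordings[[i]]
    fn <- sprintf("%s_%s_t%s.csv", r$participant_id, r$task,
                  ifelse(is.na(r$trial_index), "x", r$trial_index))
    write_recording(r, file.path(dir, fn))
    fn
  }, character(1))
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE)
  invisible(mp)
}

#' Reference trial-accuracy table
#'
#' The published per-task, per-group accuracy table of a PD-versus-control
#' mobility study (three tasks x three severity groups x four feature sets),
#' shipped as package data. Used to exercise the trial-comparison arithmetic
#' of [compare_trial_models()] against its published summary means.
#'
#' @return data.frame: task, group, feature_set, accuracy (percent).
#' @export
reference_trial_accuracies <- function() {
  utils::read.csv(system.file("extdata", "reference_trial_accuracies.csv",
                              package = "mobilitytrt"),
                  stringsAsFactors = FALSE)
}
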
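# Subtask segmentation: angular position from yaw velocity, turn detection,
# TUG six-segment split, and the 32-foot -> 2 x 16-foot split.
#
# All intervals are 0-based half-open [start_idx, end_idx) sample indices so
# that durations are (end - start) / fs and adjacent segments tile exactly.

#' Angular position from yaw angular velocity
#'
#' Cumulative trapezoidal integral of the vertical-axis angular velocity,
#' giving heading in degrees relative to the first sample.
#'
#' @param gyr_yaw angular velocity series (degrees/s), length >= 2.
#' @param fs sampling rate (Hz).
#' @return angle series in degrees, same length, first element 0.
#' @export
angular_position <- function(gyr_yaw, fs) {
  if (length(gyr_yaw) < 2) stop("angular_position: series length < 2")
  cumtrapz(gyr_yaw, fs)
}

#' Detect turns from an angle series
#'
#' A turn is a maximal interval over which the smoothed heading changes
#' monotonically by at least `min_angle_deg`. Candidate intervals are runs
#' where the smoothed yaw speed exceeds `omega_floor_dps`; each retained
#' interval is trimmed to the 5%/95% quantiles of its net angular change and
#' then extended outward to the nearest near-zero of the smoothed yaw
#' velocity. Detection is invariant to rotation sign.
#'
#' @param angle angle series (degrees) from [angular_position()].
#' @param fs sampling rate (Hz).
#' @param min_angle_deg minimum net rotation to count as a turn (default 90;
#'   protocol turns are ~180).
#' @param smooth_s moving-average window applied to the angle/velocity
#'   (seconds).
#' @param omega_floor_dps yaw-speed threshold defining candidate intervals.
#' @param quantiles trim points of the net angular change.
#' @return data.frame with columns `start_idx`, `end_idx` (0-based,
#'   half-open), ordered in time; zero rows when no turn is found.
#' @export
detect_turns <- function(angle, fs, min_angle_deg = 90, smooth_s = 0.25,
                         omega_floor_dps = 10, quantiles = c(0.05, 0.95)) {
  n <- length(angle)
  win <- max(1L, round(smooth_s * fs))
  theta <- moving_average(angle, win)
  omega <- c(diff(theta), 0) * fs
  omega <- moving_average(omega, win)
  active <- abs(omega) > omega_floor_dps
  if (!any(active)) return(empty_turns())
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    net <- theta[i1] - theta[i0]
    if (abs(net) < min_angle_deg) next
    # require a consistent rotation direction over the interval
    prog <- theta[i0:i1] - theta[i0]
    if (net < 0) prog <- -prog
    # trim to the 5%/95% quantiles of the net change
    a <- i0 + which(prog >= quantiles[1] * abs(net))[1] - 1L
    b <- i0 + which(prog >= quantiles[2] * abs(net))[1] - 1L
    if (is.na(a) || is.na(b) || b <= a) next
    # extend outward to the nearest near-zero of the smoothed velocity
    zero_tol <- omega_floor_dps / 4
    while (a > 1L && abs(omega[a - 1L]) > zero_tol) a <- a - 1L
    while (b < n && abs(omega[b + 1L]) > zero_tol) b <- b + 1L
    out[[length(out) + 1L]] <- c(start_idx = a - 1L, end_idx = b)
  }
  if (length(out) == 0L) return(empty_turns())
  df <- as.data.frame(do.call(rbind, out))
  df <- df[order(df$start_idx), , drop = FALSE]
  # enforce non-overlap (candidate runs are disjoint, but the zero-velocity
  # extension could touch a neighbour)
  if (nrow(df) > 1L) {
    for (i in 2:nrow(df)) {
      if (df$start_idx[i] < df$end_idx[i - 1L])
        df$start_idx[i] <- df$end_idx[i - 1L]
    }
  }
  rownames(df) <- NULL
  df
}

empty_turns <- function() {
  data.frame(start_idx = integer(0), end_idx = integer(0))
}

new_segmented_task <- function(rec, segments, task, trial_index = NULL) {
  stopifnot(all(segments$end_idx > segments$start_idx))
  st <- list(recording = rec, segments = segments, task = task,
             fs = rec$fs,
             trial_index = if (is.null(trial_index)) rec$trial_index else
               trial_index,
             participant_id = rec$participant_id,
             group = rec$group)
  class(st) <- "segmented_task"
  st
}

#' @export
print.segmented_task <- function(x, ...) {
  cat(sprintf("<segmented_task> %s %s trial %s: %d segments\n",
              x$participant_id, x$task,
              ifelse(is.na(x$trial_index), "-", x$trial_index),
              nrow(x$segments)))
  print(segments_df(x))
  invisible(x)
}

#' Segment table of a segmented task
#'
#' @param st a `segmented_task`.
#' @return data.frame with label, start_idx, end_idx, start_s, end_s,
#'   duration_s.
#' @export
segments_df <- function(st) {
  s <- st$segments
  s$start_s <- s$start_idx / st$fs
  s$end_s <- s$end_idx / st$fs
  s$duration_s <- s$end_s - s$start_s
  s
}

# envelope-based walking onset: first sustained exceedance of the high-pass
# oscillation envelope. Threshold is the larger of 3x the SD of the envelope
# over the leading baseline window and 0.4x the envelope's 90th percentile
# (the generated recording starts mid sit-to-stand, so a pure seated-baseline
# criterion is not available).
detect_walk_onset <- function(acc_v, fs, search_end_idx,
                              highpass_s = 0.6, env_s = 0.25,
                              baseline_s = 0.3, sustain_s = 0.5,
                              rel_frac = 0.4) {
  hp <- acc_v - moving_average(acc_v, round(highpass_s * fs))
  env <- rolling_rms(hp, round(env_s * fs))
  nb <- max(2L, round(baseline_s * fs))
  thr <- max(3 * stats::sd(env[seq_len(nb)]),
             rel_frac * stats::quantile(env, 0.9, names = FALSE))
  sustain <- max(1L, round(sustain_s * fs))
  above <- env > thr
  lim <- min(search_end_idx, length(above) - sustain + 1L)
  for (i in seq_len(max(lim, 0L))) {
    if (all(above[i:(i + sustain - 1L)])) return(i - 1L) # 0-based
  }
  NA_integer_
}

#' Segment a TUG or cogTUG recording into six subtasks
#'
#' Turns come from [detect_turns()] on the integrated yaw signal; exactly two
#' must be found. The sit-to-stand segment runs from the recording start to
#' the walking onset (oscillation-envelope criterion); stand-to-sit runs from
#' the end of the second turn to the recording end; the two walks fill the
#' remaining spans. Segments tile the full recording.
#'
#' @param rec a `sensor_recording` with task TUG or cogTUG.
#' @param min_angle_deg passed to [detect_turns()].
#' @return a `segmented_task` with six segments.
#' @export
segment_tug <- function(rec, min_angle_deg = 90) {
  if (!rec$task %in% c("TUG", "cogTUG"))
    stop("segment_tug: task must be TUG or cogTUG, got '", rec$task, "'")
  angle <- angular_position(rec$gyr_yaw, rec$fs)
  turns <- detect_turns(angle, rec$fs, min_angle_deg = min_angle_deg)
  if (nrow(turns) != 2L)
    stop("segmentation failure: expected 2 turns, found ", nrow(turns))
  n <- length(rec$acc_v)
  onset <- detect_walk_onset(rec$acc_v, rec$fs,
                             search_end_idx = turns$start_idx[1])
  if (is.na(onset) || onset <= 0L || onset >= turns$start_idx[1])
    stop("segmentation failure: could not locate walking onset")
  seg <- data.frame(
    label = c("sit_to_stand", "walk1", "turn1", "walk2", "turn2",
              "stand_to_sit"),
    start_idx = c(0L, onset, turns$start_idx[1], turns$end_idx[1],
                  turns$start_idx[2], turns$end_idx[2]),
    end_idx = c(onset, turns$start_idx[1], turns$end_idx[1],
                turns$start_idx[2], turns$end_idx[2], n),
    stringsAsFactors = FALSE
  )
  new_segmented_task(rec, seg, rec$task)
}

#' Split a 32-foot walk into two 16-foot trials
#'
#' Requires exactly three detectable turns. Trial 1 is walk 1 + turn 1 +
#' walk 2 (ending at the onset of turn 2); trial 2 is walk 3 + turn 3 +
#' walk 4 (starting at the end of turn 2). The second turn belongs to
#' neither trial. Each trial is segmented as walk / turn / walk.
#'
#' @param rec a `sensor_recording` with task `walk32ft`.
#' @param min_angle_deg passed to [detect_turns()].
#' @return list of two `segmented_task` objects (`trial_index` 1 and 2,
#'   task label `walk16ft`).
#' @export
split_32ft <- function(rec, min_angle_deg = 90) {
  if (rec$task != "walk32ft")
    stop("split_32ft: task must be walk32ft, got '", rec$task, "'")
  angle <- angular_position(rec$gyr_yaw, rec$fs)
  turns <- detect_turns(angle, rec$fs, min_angle_deg = min_angle_deg)
  if (nrow(turns) != 3L)
    stop("segmentation failure: expected 3 turns, found ", nrow(turns))
  n <- length(rec$acc_v)
  segA <- data.frame(
    label = c("walk1", "turn", "walk2"),
    start_idx = c(0L, turns$start_idx[1], turns$end_idx[1]),
    end_idx = c(turns$start_idx[1], turns$end_idx[1], turns$start_idx[2]),
    stringsAsFactors = FALSE
  )
  segB <- data.frame(
    label = c("walk1", "turn", "walk2"),
    start_idx = c(turns$end_idx[2], turns$start_idx[3], turns$end_idx[3]),
    end_idx = c(turns$start_idx[3], turns$end_idx[3], n),
    stringsAsFactors = FALSE
  )
  list(new_segmented_task(rec, segA, "walk16ft", trial_index = 1L),
       new_segmented_task(rec, segB, "walk16ft", trial_index = 2L))
}

#' Segment any recording
#'
#' Dispatches on the task label: TUG/cogTUG give one `segmented_task`,
#' `walk32ft` gives a list of two 16-foot trials.
#'
#' @param rec a `sensor_recording`.
#' @param ... passed to [segment_tug()] / [split_32ft()].
#' @return a list of `segmented_task` objects (length 1 or 2).
#' @export
segment_recording <- function(rec, ...) {
  if (rec$task == "walk32ft") split_32ft(rec, ...)
  else list(segment_tug(rec, ...))
}

#' Segment annotations for a set of recordings, as a table
#'
#' @param recordings list of `sensor_recording` (e.g. from
#'   [simulate_cohort()]).
#' @param ... passed to [segment_recording()].
#' @return data.frame: participant_id, task, trial, label, start_s, end_s;
#'   recordings that fail segmentation are skipped with a warning and listed
#'   in the `failures` attribute.
#' @export
segment_cohort <- function(recordings, ...) {
  rows <- list(); fails <- character(0)
  for (rec in recordings) {
    sts <- tryCatch(segment_recording(rec, ...), error = function(e) e)
    if (inherits(sts, "error")) {
      fails <- c(fails, sprintf("%s/%s: %s", rec$participant_id, rec$task,
                                conditionMessage(sts)))
      next
    }
    for (st in sts) {
      s <- segments_df(st)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = st$participant_id, group = st$group, task = st$task,
        trial = st$trial_index, label = s$label, start_s = s$start_s,
        end_s = s$end_s, stringsAsFactors = FALSE)
    }
  }
  if (length(fails))
    warning("segmentation failed for ", length(fails), " recording(s)")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant_id = character(0), group = character(0),
               task = character(0), trial = integer(0), label = character(0),
               start_s = numeric(0), end_s = numeric(0))
  attr(out, "failures") <- fails
  out
}
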
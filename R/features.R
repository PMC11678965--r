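# Sensor-derived quantitative measures per segmented trial.
#
# Undefined measures (too few steps, nonpositive stride regularity, ...) are
# explicit NAs, never silent zeros; extract_all() propagates them without
# aborting. All gait measures operate on mean-removed signals, so they are
# invariant to a constant accelerometer offset; the transition median is the
# documented exception.

# peak-detection convention: cadence <= ~3.3 steps/s, prominence relative to
# the segment's spread (no published thresholds exist; both configurable)
PEAK_MIN_DIST_S <- 0.3
PEAK_PROM_FRAC <- 0.5

segment_signal <- function(st, channel, label) {
  s <- st$segments
  row <- which(s$label == label)
  if (length(row) != 1L) stop("no segment labelled '", label, "'")
  idx <- (s$start_idx[row] + 1L):s$end_idx[row]
  st$recording[[channel]][idx]
}

#' Total duration of a segmented trial
#'
#' Sum of segment durations in seconds. For a contiguous TUG this equals the
#' recording span; for a 16-foot trial it is walk + turn + walk (the omitted
#' central turn of the 32-foot task is not counted).
#'
#' @param st a `segmented_task`.
#' @return seconds.
#' @export
total_duration <- function(st) {
  sum(segments_df(st)$duration_s)
}

#' Count steps in a walking-segment acceleration signal
#'
#' Steps are peaks of the mean-removed signal with a minimum inter-peak
#' distance of 0.3 s and a minimum prominence of half the segment SD.
#'
#' @param acc acceleration series (one walking segment).
#' @param fs sampling rate (Hz).
#' @return integer step count (0 for a flat signal).
#' @export
count_steps <- function(acc, fs) {
  length(step_peaks(acc, fs))
}

step_peaks <- function(acc, fs) {
  x <- acc - mean(acc)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(integer(0))
  find_peaks(x, min_dist = round(PEAK_MIN_DIST_S * fs),
             min_prominence = PEAK_PROM_FRAC * s)
}

#' Mean step and stride duration
#'
#' Step duration is the mean interval between consecutive detected peaks;
#' stride duration the mean interval between alternate peaks.
#'
#' @param acc acceleration series (one walking segment).
#' @param fs sampling rate (Hz).
#' @return list(step_duration_s, stride_duration_s); both `NA` (undefined
#'   measure) when fewer than 3 peaks are detected.
#' @export
step_stride_timing <- function(acc, fs) {
  pk <- step_peaks(acc, fs)
  if (length(pk) < 3L)
    return(list(step_duration_s = NA_real_, stride_duration_s = NA_real_))
  tt <- pk / fs
  list(step_duration_s = mean(diff(tt)),
       stride_duration_s = mean(tt[-(1:2)] - tt[seq_len(length(tt) - 2L)]))
}

#' Step and stride regularity from the acceleration autocorrelation
#'
#' Unbiased autocorrelation normalized to 1 at lag 0; step regularity is the
#' value at the first dominant positive-lag peak (one step lag), stride
#' regularity the value at the second (one stride lag). The peak search is
#' restricted to lags of 0.2 to 2.5 s.
#'
#' @param acc acceleration series (>= ~3 stride periods recommended).
#' @param fs sampling rate (Hz).
#' @param lag_range_s search window for autocorrelation peaks (seconds).
#' @return list(step_regularity, stride_regularity), each in [-1, 1]; `NA`
#'   when no two peaks exist.
#' @export
regularity <- function(acc, fs, lag_range_s = c(0.2, 2.5)) {
  undef <- list(step_regularity = NA_real_, stride_regularity = NA_real_)
  max_lag <- min(length(acc) - 1L, round(lag_range_s[2] * fs))
  if (max_lag < round(lag_range_s[1] * fs) + 2L) return(undef)
  r <- autocorr_unbiased(acc, max_lag)
  if (anyNA(r)) return(undef)
  lo <- round(lag_range_s[1] * fs)
  # peaks of the autocorrelation, modest prominence to skip noise ripples
  pk <- find_peaks(r, min_dist = max(2L, round(0.1 * fs)),
                   min_prominence = 0.05)
  pk <- pk[pk - 1L >= lo] # r[i] is lag i-1
  if (length(pk) < 2L) return(undef)
  list(step_regularity = r[pk[1]], stride_regularity = r[pk[2]])
}

#' Step symmetry
#'
#' Proximity of the step/stride regularity ratio to 1, mapped as
#' `min(r, 1/r)` so the result is symmetric in the two regularities and lies
#' in (0, 1].
#'
#' @param step_regularity,stride_regularity regularity values.
#' @return symmetry in (0, 1], or `NA` when stride regularity is not
#'   positive (undefined measure).
#' @export
step_symmetry <- function(step_regularity, stride_regularity) {
  if (is.na(step_regularity) || is.na(stride_regularity) ||
      stride_regularity <= 0 || step_regularity <= 0)
    return(NA_real_)
  r <- step_regularity / stride_regularity
  min(r, 1 / r)
}

#' Dominant frequency of a signal
#'
#' Frequency of the largest-amplitude DFT coefficient, DC excluded (the mean
#' is removed first). Resolution is `fs / length(signal)`.
#'
#' @param signal numeric series.
#' @param fs sampling rate (Hz).
#' @return frequency in Hz.
#' @export
dominant_frequency <- function(signal, fs) {
  n <- length(signal)
  if (n < 4L) return(NA_real_)
  x <- signal - mean(signal)
  amp <- abs(stats::fft(x))[2:(n %/% 2L + 1L)]
  which.max(amp) * fs / n
}

#' PSD peak measures
#'
#' Welch PSD (Hann taper, `min(N, 256)`-sample segments, 50% overlap);
#' amplitude is the PSD maximum in the locomotor band (0.5 to 5 Hz), width
#' the full width at half that maximum, slope the least-squares slope of the
#' PSD from the peak down to the first point at or below half maximum above
#' the peak frequency.
#'
#' @param signal walking-segment series.
#' @param fs sampling rate (Hz).
#' @param band frequency band searched for the peak (Hz).
#' @return list(amplitude, width_hz, slope).
#' @export
psd_peak_measures <- function(signal, fs, band = c(0.5, 5)) {
  undef <- list(amplitude = NA_real_, width_hz = NA_real_, slope = NA_real_)
  if (length(signal) < 16L) return(undef)
  w <- welch_psd(signal, fs)
  inband <- which(w$freq >= band[1] & w$freq <= band[2])
  if (length(inband) < 3L) return(undef)
  ipk <- inband[which.max(w$psd[inband])]
  pmax_ <- w$psd[ipk]
  half <- pmax_ / 2
  # full width at half maximum around the peak, over the whole spectrum
  left <- ipk
  while (left > 1L && w$psd[left - 1L] > half) left <- left - 1L
  right <- ipk
  nf <- length(w$freq)
  while (right < nf && w$psd[right + 1L] > half) right <- right + 1L
  width <- w$freq[right] - w$freq[left]
  df <- w$freq[2] - w$freq[1]
  width <- max(width, df) # a line peak still spans one bin
  # slope from the peak to the first point <= half max above it
  hi <- right
  if (hi < nf) hi <- hi + 1L
  slope <- if (hi > ipk) {
    stats::coef(stats::lm(w$psd[ipk:hi] ~ w$freq[ipk:hi]))[2]
  } else NA_real_
  list(amplitude = pmax_, width_hz = width, slope = unname(slope))
}

#' Chair-transition measures
#'
#' Descriptives of a sit-to-stand or stand-to-sit acceleration segment:
#' duration, range (max - min), jerk (RMS of the finite-difference
#' derivative, g/s), SD and median. The median is the one measure that is
#' sensitive to a constant accelerometer offset.
#'
#' @param acc acceleration series (one transition segment).
#' @param fs sampling rate (Hz).
#' @return list(duration_s, range, jerk, sd, median).
#' @export
transition_measures <- function(acc, fs) {
  n <- length(acc)
  jerk <- if (n >= 2L) sqrt(mean((diff(acc) * fs)^2)) else NA_real_
  list(duration_s = n / fs,
       range = max(acc) - min(acc),
       jerk = jerk,
       sd = stats::sd(acc),
       median = stats::median(acc))
}

#' Turn measures
#'
#' Duration, in-turn step count (vertical acceleration peaks), net yaw
#' amplitude in degrees (from the integrated angular position), and dominant
#' yaw-velocity frequency.
#'
#' @param st a `segmented_task`.
#' @param label turn segment label (e.g. `"turn1"`, `"turn"`).
#' @return list(duration_s, step_count, amplitude_yaw_deg,
#'   dominant_frequency_hz).
#' @export
turn_measures <- function(st, label) {
  yaw <- segment_signal(st, "gyr_yaw", label)
  accv <- segment_signal(st, "acc_v", label)
  fs <- st$fs
  amp <- if (length(yaw) >= 2L) {
    ang <- angular_position(yaw, fs)
    abs(ang[length(ang)] - ang[1])
  } else NA_real_
  list(duration_s = length(yaw) / fs,
       step_count = count_steps(accv, fs),
       amplitude_yaw_deg = amp,
       dominant_frequency_hz = dominant_frequency(yaw, fs))
}

walk_measure_block <- function(st, label) {
  fs <- st$fs
  out <- list()
  for (sfx in c("v", "ap")) {
    ch <- c(v = "acc_v", ap = "acc_ap")[[sfx]]
    x <- segment_signal(st, ch, label)
    timing <- step_stride_timing(x, fs)
    reg <- regularity(x, fs)
    psd <- psd_peak_measures(x, fs)
    out[[paste(label, "step_count", sfx, sep = "_")]] <- count_steps(x, fs)
    out[[paste(label, "step_duration", sfx, sep = "_")]] <-
      timing$step_duration_s
    out[[paste(label, "stride_duration", sfx, sep = "_")]] <-
      timing$stride_duration_s
    out[[paste(label, "step_regularity", sfx, sep = "_")]] <-
      reg$step_regularity
    out[[paste(label, "stride_regularity", sfx, sep = "_")]] <-
      reg$stride_regularity
    out[[paste(label, "step_symmetry", sfx, sep = "_")]] <-
      step_symmetry(reg$step_regularity, reg$stride_regularity)
    out[[paste(label, "psd_amplitude", sfx, sep = "_")]] <- psd$amplitude
    out[[paste(label, "psd_width", sfx, sep = "_")]] <- psd$width_hz
    out[[paste(label, "psd_slope", sfx, sep = "_")]] <- psd$slope
  }
  out
}

transition_measure_block <- function(st, label) {
  fs <- st$fs
  out <- list()
  for (sfx in c("v", "ap")) {
    ch <- c(v = "acc_v", ap = "acc_ap")[[sfx]]
    x <- segment_signal(st, ch, label)
    tm <- transition_measures(x, fs)
    out[[paste(label, "range", sfx, sep = "_")]] <- tm$range
    out[[paste(label, "jerk", sfx, sep = "_")]] <- tm$jerk
    out[[paste(label, "sd", sfx, sep = "_")]] <- tm$sd
    out[[paste(label, "median", sfx, sep = "_")]] <- tm$median
  }
  out
}

turn_measure_block <- function(st, label) {
  tm <- turn_measures(st, label)
  out <- list()
  out[[paste0(label, "_step_count")]] <- tm$step_count
  out[[paste0(label, "_amplitude_yaw")]] <- tm$amplitude_yaw_deg
  out[[paste0(label, "_dominant_frequency")]] <- tm$dominant_frequency_hz
  out
}

#' Extract all measures for one segmented trial
#'
#' Emits the full measure schema as long-format rows: total and subtask
#' durations, walking measures for each walk segment (vertical and
#' anteroposterior channels), PSD peak measures, chair-transition measures
#' (TUG/cogTUG only) and turn measures. Undefined measures propagate as NA
#' values.
#'
#' @param st a `segmented_task`.
#' @return data.frame: participant_id, group, task, trial, measure_name,
#'   value.
#' @export
extract_all <- function(st) {
  s <- segments_df(st)
  vals <- list(total_duration = total_duration(st))
  for (i in seq_len(nrow(s)))
    vals[[paste0(s$label[i], "_duration")]] <- s$duration_s[i]
  for (lab in s$label[grepl("^walk", s$label)])
    vals <- c(vals, walk_measure_block(st, lab))
  for (lab in s$label[grepl("_to_", s$label)])
    vals <- c(vals, transition_measure_block(st, lab))
  for (lab in s$label[grepl("^turn", s$label)])
    vals <- c(vals, turn_measure_block(st, lab))
  data.frame(
    participant_id = st$participant_id,
    group = if (is.null(st$group) || is.na(st$group)) NA_character_ else
      st$group,
    task = st$task,
    trial = st$trial_index,
    measure_name = names(vals),
    value = as.numeric(unlist(vals)),
    stringsAsFactors = FALSE
  )
}

#' Segment and extract measures for a whole cohort
#'
#' @param recordings list of `sensor_recording`.
#' @param ... passed to [segment_recording()].
#' @return long-format measure table (see [extract_all()]); failed
#'   recordings are skipped with a warning, listed in the `failures`
#'   attribute.
#' @export
extract_cohort <- function(recordings, ...) {
  rows <- list(); fails <- character(0)
  for (rec in recordings) {
    sts <- tryCatch(segment_recording(rec, ...), error = function(e) e)
    if (inherits(sts, "error")) {
      fails <- c(fails, sprintf("%s/%s: %s", rec$participant_id, rec$task,
                                conditionMessage(sts)))
      next
    }
    for (st in sts) rows[[length(rows) + 1L]] <- extract_all(st)
  }
  if (length(fails))
    warning("extraction skipped ", length(fails), " recording(s)")
  out <- do.call(rbind, rows)
  attr(out, "failures") <- fails
  out
}
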
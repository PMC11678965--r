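# Synthetic six-axis IMU recordings with known ground truth.
#
# A recording is a stated world, not a fit to data: segment durations come
# from the group profile (scaled per participant and trial), gait is a
# per-step pulse train with one vertical/AP peak per step, turns are
# raised-cosine yaw-velocity pulses whose trapezoidal integral is 180 degrees
# by construction, and chair transitions are single low-frequency lobes.

TASKS <- c("TUG", "cogTUG", "walk32ft")

# waveform constants (g, degrees/s); exported as part of the ground truth so
# tests can compare against construction values
WALK_AMP_V <- 0.25
WALK_AMP_AP <- 0.15
WALK_AMP_ML <- 0.08
TURN_STEP_ATTEN <- 0.7
TRANS_AMP_V <- 0.4
TRANS_AMP_AP <- 0.5
HARMONIC_FRAC <- 0.15 # keeps the per-step pulse unimodal (needs <= 0.2)

new_sensor_recording <- function(fs, series, task, trial_index,
                                 participant_id, group = NA_character_,
                                 truth = NULL) {
  rec <- list(fs = fs, acc_v = series$acc_v, acc_ml = series$acc_ml,
              acc_ap = series$acc_ap, gyr_yaw = series$gyr_yaw,
              gyr_pitch = series$gyr_pitch, gyr_roll = series$gyr_roll,
              task = task, trial_index = trial_index,
              participant_id = participant_id, group = group, truth = truth)
  class(rec) <- "sensor_recording"
  validate_sensor_recording(rec)
}

validate_sensor_recording <- function(rec) {
  chans <- c("acc_v", "acc_ml", "acc_ap", "gyr_yaw", "gyr_pitch", "gyr_roll")
  lens <- vapply(rec[chans], length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("sensor_recording: channels differ in length")
  if (rec$fs <= 0) stop("sensor_recording: fs must be positive")
  if (lens[1] < rec$fs) stop("sensor_recording: shorter than 1 s")
  if (anyNA(unlist(rec[chans], use.names = FALSE)))
    stop("sensor_recording: missing samples")
  if (!rec$task %in% TASKS)
    stop("sensor_recording: unknown task '", rec$task, "'")
  invisible(rec)
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %s %s trial %s: %.2f s @ %g Hz\n",
              x$participant_id, x$task,
              ifelse(is.na(x$trial_index), "-", x$trial_index),
              length(x$acc_v) / x$fs, x$fs))
  invisible(x)
}

# ordered segment plan (label, duration) for one recording
segment_plan <- function(params, task, trial_index) {
  scale <- params$walk_speed_scale
  if (task == "cogTUG") scale <- scale * params$cogtug_scale
  if (task %in% c("TUG", "cogTUG")) {
    if (trial_index == 2) scale <- scale * params$trial2_multiplier
    labels <- c("sit_to_stand", "walk1", "turn1", "walk2", "turn2",
                "stand_to_sit")
    durs <- scale * c(params$transition_duration_s, params$base_walk_s,
                      params$turn_duration_s, params$base_walk_s,
                      params$turn_duration_s, params$transition_duration_s)
  } else {
    labels <- c("walk1", "turn1", "walk2", "turn2", "walk3", "turn3", "walk4")
    durs <- scale * c(params$base_walk_s, params$turn_duration_s,
                      params$base_walk_s, params$turn_duration_s,
                      params$base_walk_s, params$turn_duration_s,
                      params$base_walk_s)
    # fatigue in the back-to-back second 16-foot trial (walk3, turn3, walk4)
    durs[5:7] <- durs[5:7] * params$walk32_trial2_multiplier
  }
  data.frame(label = labels, duration_s = durs, stringsAsFactors = FALSE)
}

# per-step pulse: unimodal, peak mid-step, fundamental at the step rate plus
# one harmonic
step_pulse_shape <- function(u, h = HARMONIC_FRAC) {
  (1 - h) * 0.5 * (1 - cos(2 * pi * u)) + h * 0.5 * (1 - cos(4 * pi * u))
}

#' Synthetic steady-gait acceleration signal
#'
#' Generates a walking-only vertical (or anteroposterior) acceleration trace:
#' a train of one-per-step unimodal pulses with optional timing jitter,
#' amplitude jitter and alternate-step asymmetry. Useful as a noiseless
#' closed-form test signal.
#'
#' @param duration_s length of the signal in seconds.
#' @param step_rate_hz steps per second (twice the stride rate).
#' @param fs sampling rate (Hz).
#' @param amp pulse amplitude (g).
#' @param cv coefficient of variation of step durations.
#' @param asymmetry_ratio amplitude ratio of every other step, in (0, 1].
#' @param amplitude_jitter relative per-step amplitude jitter SD.
#' @return numeric vector with attribute `step_times` (true mid-step peak
#'   times, seconds).
#' @export
simulate_walk_signal <- function(duration_s, step_rate_hz = 2, fs = 100,
                                 amp = WALK_AMP_V, cv = 0,
                                 asymmetry_ratio = 1, amplitude_jitter = 0) {
  st <- draw_steps(duration_s, step_rate_hz, cv)
  render_steps(st, duration_s, fs, amp, asymmetry_ratio, amplitude_jitter)
}

# draw step boundaries covering [0, span]; returns data.frame(start, dur)
draw_steps <- function(span, step_rate_hz, cv) {
  mean_T <- 1 / step_rate_hz
  starts <- numeric(0); durs <- numeric(0)
  t <- 0
  while (t < span) {
    z <- if (cv > 0) max(-3, min(3, stats::rnorm(1))) else 0
    Tk <- mean_T * (1 + cv * z)
    starts <- c(starts, t); durs <- c(durs, Tk)
    t <- t + Tk
  }
  data.frame(start = starts, dur = durs)
}

# render a step table into a sampled pulse train
render_steps <- function(st, span, fs, amp, asymmetry_ratio,
                         amplitude_jitter) {
  n <- round(span * fs)
  tt <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  amps <- numeric(nrow(st))
  for (k in seq_len(nrow(st))) {
    a <- amp
    if (k %% 2 == 0) a <- a * asymmetry_ratio
    if (amplitude_jitter > 0)
      a <- a * (1 + amplitude_jitter * max(-3, min(3, stats::rnorm(1))))
    amps[k] <- a
    idx <- which(tt >= st$start[k] & tt < st$start[k] + st$dur[k])
    if (length(idx))
      x[idx] <- a * step_pulse_shape((tt[idx] - st$start[k]) / st$dur[k])
  }
  peak_t <- st$start + st$dur / 2
  keep <- peak_t < span
  structure(x, step_times = peak_t[keep], step_amps = amps[keep])
}

raised_cosine_pulse <- function(n_samples) {
  u <- (seq_len(n_samples) - 0.5) / n_samples
  0.5 * (1 - cos(2 * pi * u))
}

#' Simulate one task recording
#'
#' Builds a six-axis 100 Hz recording with the task's subtask structure:
#' for TUG/cogTUG a sit-to-stand transient, two 8-foot walks separated by a
#' ~180 degree turn each way, and a stand-to-sit transient; for the 32-foot
#' walk four 8-foot bouts separated by three turns, no chair transitions.
#' Turn yaw pulses integrate to 180 degrees by construction; trial-2
#' durations are scaled by `trial2_multiplier`. Ground truth (segment
#' boundaries, step peak times, turn signs) is attached as `$truth`.
#'
#' @param params a [group_params()] object.
#' @param task `"TUG"`, `"cogTUG"` or `"walk32ft"`.
#' @param trial_index 1 or 2 (ignored for `walk32ft`, which contains both
#'   16-foot trials).
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @param subject_scale per-participant duration multiplier (drawn by
#'   [simulate_cohort()]).
#' @param participant_id identifier stored in the recording.
#' @param fs sampling rate (Hz).
#' @return a `sensor_recording`.
#' @export
simulate_recording <- function(params, task, trial_index = 1, seed = NULL,
                               subject_scale = 1, participant_id = "P01",
                               fs = 100) {
  stopifnot(inherits(params, "group_params"))
  if (!task %in% TASKS)
    stop("unknown task '", task, "'; expected one of ",
         paste(TASKS, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  plan <- segment_plan(params, task, trial_index)
  plan$duration_s <- plan$duration_s * subject_scale
  nseg <- round(plan$duration_s * fs)
  plan$duration_s <- nseg / fs # snap to the sample grid
  ends <- cumsum(plan$duration_s)
  plan$start_s <- c(0, ends[-length(ends)])
  plan$end_s <- ends
  n <- sum(nseg)

  acc_v <- numeric(n); acc_ap <- numeric(n); acc_ml <- numeric(n)
  gyr_yaw <- numeric(n); gyr_pitch <- numeric(n); gyr_roll <- numeric(n)

  seg_idx <- function(k) {
    if (nseg[k] == 0L) return(integer(0))
    (sum(nseg[seq_len(k - 1)]) + 1L):sum(nseg[seq_len(k)])
  }

  # stepping span: contiguous run of walk/turn segments
  stepping <- grepl("^(walk|turn)", plan$label)
  span_start <- plan$start_s[which(stepping)[1]]
  span_end <- plan$end_s[max(which(stepping))]
  step_rate <- 2 * params$step_frequency_hz
  st <- draw_steps(span_end - span_start, step_rate, params$step_frequency_cv)
  walk_v <- render_steps(st, span_end - span_start, fs, WALK_AMP_V,
                         params$asymmetry_ratio, params$amplitude_jitter)
  step_times <- attr(walk_v, "step_times") + span_start
  step_amps <- attr(walk_v, "step_amps")
  # AP shares the step timing at reduced amplitude; ML alternates per stride
  scale_ap <- WALK_AMP_AP / WALK_AMP_V
  walk_ap <- as.numeric(walk_v) * scale_ap
  walk_ml <- numeric(length(walk_v))
  tt_span <- (seq_along(walk_v) - 1) / fs
  for (k in seq_len(nrow(st))) {
    idx <- which(tt_span >= st$start[k] & tt_span < st$start[k] + st$dur[k])
    if (length(idx)) {
      sgn <- if (k %% 2 == 0) -1 else 1
      walk_ml[idx] <- sgn * WALK_AMP_ML *
        step_pulse_shape((tt_span[idx] - st$start[k]) / st$dur[k])
    }
  }
  span_idx <- (round(span_start * fs) + 1L):(round(span_end * fs))
  # attenuate stepping during turns
  atten <- rep(1, length(span_idx))
  for (k in which(grepl("^turn", plan$label))) {
    rel <- seg_idx(k) - span_idx[1] + 1L
    atten[rel] <- TURN_STEP_ATTEN
  }
  acc_v[span_idx] <- as.numeric(walk_v) * atten
  acc_ap[span_idx] <- walk_ap * atten
  acc_ml[span_idx] <- walk_ml * atten

  # turns: raised-cosine yaw pulse integrating to 180 deg, alternating sign
  turn_rows <- which(grepl("^turn", plan$label))
  turn_sign <- rep_len(c(1, -1), length(turn_rows))
  for (j in seq_along(turn_rows)) {
    k <- turn_rows[j]
    idx <- seg_idx(k)
    Tk <- plan$duration_s[k]
    omega_max <- 2 * 180 / Tk
    gyr_yaw[idx] <- turn_sign[j] * omega_max * raised_cosine_pulse(length(idx))
  }

  # chair transitions: single low-frequency lobes on AP and vertical
  for (k in which(grepl("_to_", plan$label))) {
    idx <- seg_idx(k)
    pulse <- raised_cosine_pulse(length(idx))
    sgn <- if (plan$label[k] == "sit_to_stand") 1 else -1
    acc_ap[idx] <- acc_ap[idx] + sgn * TRANS_AMP_AP * pulse
    acc_v[idx] <- acc_v[idx] + sgn * TRANS_AMP_V * pulse
  }

  if (params$noise_sd_g > 0) {
    acc_v <- acc_v + stats::rnorm(n, 0, params$noise_sd_g)
    acc_ap <- acc_ap + stats::rnorm(n, 0, params$noise_sd_g)
    acc_ml <- acc_ml + stats::rnorm(n, 0, params$noise_sd_g)
  }
  if (params$gyro_noise_sd_dps > 0) {
    gyr_yaw <- gyr_yaw + stats::rnorm(n, 0, params$gyro_noise_sd_dps)
    gyr_pitch <- gyr_pitch + stats::rnorm(n, 0, params$gyro_noise_sd_dps)
    gyr_roll <- gyr_roll + stats::rnorm(n, 0, params$gyro_noise_sd_dps)
  }

  truth <- list(
    segments = plan[, c("label", "start_s", "end_s", "duration_s")],
    step_times = step_times,
    step_amps = step_amps,
    step_rate_hz = step_rate,
    turn_signs = turn_sign,
    turn_angle_deg = 180,
    transition_amp = c(v = TRANS_AMP_V, ap = TRANS_AMP_AP)
  )
  new_sensor_recording(
    fs = fs,
    series = list(acc_v = acc_v, acc_ml = acc_ml, acc_ap = acc_ap,
                  gyr_yaw = gyr_yaw, gyr_pitch = gyr_pitch,
                  gyr_roll = gyr_roll),
    task = task,
    trial_index = if (task == "walk32ft") NA_integer_ else
      as.integer(trial_index),
    participant_id = participant_id,
    group = params$group_label,
    truth = truth
  )
}

#' Simulate a multi-group cohort of recordings
#'
#' Two TUG and two cogTUG trials plus one 32-foot walk per participant. Each
#' participant gets a single log-normal speed offset, drawn once and shared
#' across trials and tasks; this between-subject variance is what makes
#' downstream ICCs nonzero.
#'
#' @param group_specs list of `list(params = group_params, n = integer)`.
#' @param seed integer seed.
#' @param tasks subset of `c("TUG", "cogTUG", "walk32ft")`.
#' @return list of `sensor_recording` with a `manifest` attribute
#'   (data.frame: participant_id, group, task, trial).
#' @export
simulate_cohort <- function(group_specs, seed = 1,
                            tasks = c("TUG", "cogTUG", "walk32ft")) {
  if (length(group_specs) == 0L) stop("simulate_cohort: empty group spec")
  tasks <- match.arg(tasks, TASKS, several.ok = TRUE)
  set.seed(seed)
  recs <- list()
  man <- list()
  for (gs in group_specs) {
    stopifnot(inherits(gs$params, "group_params"), gs$n >= 1)
    p <- gs$params
    for (i in seq_len(gs$n)) {
      pid <- sprintf("%s_%03d", p$group_label, i)
      subject_scale <- exp(stats::rnorm(1, 0, p$between_subject_sd))
      for (task in tasks) {
        trials <- if (task == "walk32ft") NA_integer_ else 1:2
        for (tr in trials) {
          rec <- simulate_recording(p, task, trial_index = tr, seed = NULL,
                                    subject_scale = subject_scale,
                                    participant_id = pid)
          recs[[length(recs) + 1L]] <- rec
          man[[length(man) + 1L]] <- data.frame(
            participant_id = pid, group = p$group_label, task = task,
            trial = tr, stringsAsFactors = FALSE)
        }
      }
    }
  }
  attr(recs, "manifest") <- do.call(rbind, man)
  recs
}

#' Simulate a two-way measure table
#'
#' Direct generative twin of the agreement-ICC ANOVA model:
#' `Y_ij = mu + p_i + t_j + e_ij`, with participant effects
#' `p_i ~ N(0, sigma_p^2)`, fixed centered trial offsets spaced `sigma_t`
#' apart, and residuals `e_ij ~ N(0, sigma_e^2)`. With `sigma_t = 0` the
#' expected ICC is `sigma_p^2 / (sigma_p^2 + sigma_e^2)`.
#'
#' @param vc a [variance_components()] object.
#' @param n number of participants (>= 2).
#' @param k number of trials (>= 2).
#' @param seed integer seed.
#' @param measure_name measure label for the output rows.
#' @return long-format data.frame: participant_id, trial, value.
#' @export
simulate_measure_table <- function(vc, n, k = 2, seed = 1,
                                   measure_name = "synthetic") {
  stopifnot(inherits(vc, "variance_components"))
  if (n < 2 || k < 2)
    stop("simulate_measure_table: need n >= 2 and k >= 2 (ICC undefined)")
  if (!is.null(seed)) set.seed(seed)
  p_i <- stats::rnorm(n, 0, vc$sigma_p)
  t_j <- vc$sigma_t * (seq_len(k) - (k + 1) / 2)
  e <- matrix(stats::rnorm(n * k, 0, vc$sigma_e), n, k)
  y <- vc$mu + outer(p_i, t_j, `+`) + e
  data.frame(
    participant_id = rep(sprintf("P%03d", seq_len(n)), times = k),
    trial = rep(seq_len(k), each = n),
    measure_name = measure_name,
    value = as.vector(y),
    stringsAsFactors = FALSE
  )
}
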
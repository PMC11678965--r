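# measure extraction: closed-form step/regularity/spectral checks against
# the generator's ground truth, plus the module's invariance properties.

fake_segmented <- function(acc_v, acc_ap, fs = 100, labels = "walk1") {
  n <- length(acc_v)
  rec <- mobilitytrt:::new_sensor_recording(
    fs = fs,
    series = list(acc_v = acc_v, acc_ml = numeric(n), acc_ap = acc_ap,
                  gyr_yaw = numeric(n), gyr_pitch = numeric(n),
                  gyr_roll = numeric(n)),
    task = "TUG", trial_index = 1L, participant_id = "fake")
  bounds <- round(seq(0, n, length.out = length(labels) + 1))
  seg <- data.frame(label = labels, start_idx = bounds[-length(bounds)],
                    end_idx = bounds[-1], stringsAsFactors = FALSE)
  mobilitytrt:::new_segmented_task(rec, seg, "TUG")
}

test_that("step counting and timing recover the generated gait", {
  x <- simulate_walk_signal(5, step_rate_hz = 2, fs = 100)
  expect_identical(count_steps(x, 100), 10L)
  expect_identical(count_steps(rep(0.3, 500), 100), 0L)

  tim <- step_stride_timing(x, 100)
  expect_equal(tim$step_duration_s, 0.5, tolerance = 0.01)
  expect_equal(tim$stride_duration_s, 1.0, tolerance = 0.01)
  expect_equal(tim$stride_duration_s / tim$step_duration_s, 2,
               tolerance = 1e-6)

  set.seed(3)
  xj <- simulate_walk_signal(10, 2, 100, cv = 0.08)
  truth_t <- attr(xj, "step_times")
  expect_lte(abs(count_steps(xj, 100) - length(truth_t)), 1)
  timj <- step_stride_timing(xj, 100)
  expect_lt(abs(timj$step_duration_s - mean(diff(truth_t))) /
              mean(diff(truth_t)), 0.05)

  expect_true(is.na(step_stride_timing(rep(0, 300), 100)$step_duration_s))
})

test_that("regularity reflects periodicity and asymmetry", {
  x <- simulate_walk_signal(10, 2, 100)
  r <- regularity(x, 100)
  expect_equal(r$stride_regularity, 1, tolerance = 0.01)
  expect_equal(r$step_regularity, 1, tolerance = 0.01)
  expect_equal(step_symmetry(r$step_regularity, r$stride_regularity), 1,
               tolerance = 0.02)

  # alternating-amplitude gait: step autocorrelation peak drops below the
  # stride peak
  xa <- simulate_walk_signal(10, 2, 100, asymmetry_ratio = 0.6)
  ra <- regularity(xa, 100)
  expect_lt(ra$step_regularity, ra$stride_regularity)

  # white noise: no gait structure
  set.seed(11)
  rn <- regularity(rnorm(1000), 100)
  vals <- unlist(rn)
  expect_true(all(is.na(vals) | abs(vals) < 0.2))
})

test_that("regularity and symmetry stay in bounds on 1000 random inputs", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(250:600, 1)
    kind <- i %% 3
    x <- if (kind == 0) rnorm(n)
    else if (kind == 1) sin(2 * pi * runif(1, 1, 3) * seq_len(n) / 100) +
        rnorm(n, 0, runif(1, 0, 1))
    else rep(runif(1, -1, 1), n)
    r <- regularity(x, 100)
    v <- unlist(r)
    expect_true(all(is.na(v) | (v >= -1 & v <= 1)))
    s <- step_symmetry(r$step_regularity, r$stride_regularity)
    expect_true(is.na(s) || (s > 0 && s <= 1))
  }
  expect_equal(step_symmetry(0.8, 0.8), 1)
  expect_equal(step_symmetry(0.5, 1.0), 0.5)
  expect_equal(step_symmetry(1.0, 0.5), 0.5)
  expect_true(is.na(step_symmetry(0.5, -0.2)))
})

test_that("dominant frequency picks the strongest spectral line", {
  fs <- 100; tt <- seq(0, 10, by = 1 / fs)
  expect_equal(dominant_frequency(sin(2 * pi * 1.8 * tt), fs), 1.8,
               tolerance = 0.1)
  two <- sin(2 * pi * 1 * tt) + 2 * sin(2 * pi * 3 * tt)
  expect_equal(dominant_frequency(two, fs), 3, tolerance = 0.1)
  # raised-cosine turn pulse: dominant frequency = 1 / duration
  rec <- simulate_recording(noiseless_params(), "TUG", 1, seed = 2)
  st <- segment_tug(rec)
  yaw <- mobilitytrt:::segment_signal(st, "gyr_yaw", "turn1")
  Tdur <- length(yaw) / fs
  expect_lt(abs(dominant_frequency(yaw, fs) - 1 / Tdur), fs / length(yaw))
})

test_that("PSD peak measures behave like a spectrum should", {
  fs <- 100
  tt <- seq_len(256) / fs
  tone <- sin(2 * pi * 2 * tt)
  pt <- psd_peak_measures(tone, fs)
  df <- fs / 256
  expect_lte(pt$width_hz, 2 * df)
  # heavily averaged broadband noise: flat spectrum, so the half-maximum
  # width spans far more bins than a spectral line
  set.seed(5)
  broad <- rnorm(256 * 64)
  pb <- psd_peak_measures(broad, fs)
  expect_gt(pb$width_hz, 5 * pt$width_hz)

  # independent single-segment Hann periodogram oracle (direct DFT)
  set.seed(6)
  sig <- sin(2 * pi * 2 * tt) + rnorm(256, 0, 0.3)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(256) / 257))
  seg <- (sig - mean(sig))
  seg <- (seg - mean(seg)) * w
  k <- 0:255
  dft_bin <- function(m) sum(seg * exp(-2i * pi * m * k / 256))
  pgram <- vapply(1:128, function(m) 2 * abs(dft_bin(m))^2 / (sum(w^2) * fs),
                  numeric(1))
  oracle_amp <- max(pgram[(1:128) * df >= 0.5 & (1:128) * df <= 5])
  ps <- psd_peak_measures(sig, fs)
  expect_lt(abs(ps$amplitude - oracle_amp) / oracle_amp, 0.1)
})

test_that("transition measures match their closed forms and generator truth", {
  fs <- 100
  const <- transition_measures(rep(0.25, 200), fs)
  expect_equal(const$range, 0)
  expect_equal(const$jerk, 0)
  expect_equal(const$sd, 0)
  expect_equal(const$median, 0.25)

  a <- 0.8
  ramp <- a * seq_len(300) / fs
  expect_equal(transition_measures(ramp, fs)$jerk, a, tolerance = 1e-9)

  rec <- simulate_recording(noiseless_params(), "TUG", 1, seed = 4)
  tr <- rec$truth$segments
  row <- tr[tr$label == "sit_to_stand", ]
  idx <- (round(row$start_s * fs) + 1L):round(row$end_s * fs)
  tm <- transition_measures(rec$acc_ap[idx], fs)
  expect_equal(tm$range, mobilitytrt:::TRANS_AMP_AP, tolerance = 0.05)
})

test_that("turn measures recover angle, steps and frequency", {
  rec <- simulate_recording(noiseless_params(), "TUG", 1, seed = 2)
  st <- segment_tug(rec)
  tm <- turn_measures(st, "turn1")
  expect_lt(abs(tm$amplitude_yaw_deg - 180), 10)
  truth <- rec$truth
  tt <- truth$segments[truth$segments$label == "turn1", ]
  n_truth <- sum(truth$step_times >= tt$start_s & truth$step_times < tt$end_s)
  expect_lte(abs(tm$step_count - n_truth), 1)
  # a rotation-free span has zero net yaw amplitude
  stz <- fake_segmented(simulate_walk_signal(4, 2, 100),
                        simulate_walk_signal(4, 2, 100) * 0.6,
                        labels = "turn1")
  expect_equal(turn_measures(stz, "turn1")$amplitude_yaw_deg, 0)
})

test_that("extract_all emits the full schema exactly once per trial", {
  rec <- simulate_recording(group_params(), "TUG", 1, seed = 1)
  m <- extract_all(segment_tug(rec))
  expect_false(any(duplicated(m$measure_name)))
  expect_true(all(c("total_duration", "sit_to_stand_duration",
                    "walk1_step_count_v", "walk2_psd_slope_ap",
                    "turn2_amplitude_yaw", "stand_to_sit_jerk_v")
                  %in% m$measure_name))
  w <- split_32ft(simulate_recording(group_params(), "walk32ft", seed = 7))
  m16 <- extract_all(w[[1]])
  expect_true(all(c("walk1_step_regularity_v", "walk2_step_regularity_v")
                  %in% m16$measure_name))
  expect_identical(sum(grepl("^turn_amplitude", m16$measure_name)), 1L)
  expect_false(any(grepl("_to_", m16$measure_name)))
})

test_that("flat signals yield durations but undefined gait measures", {
  st <- fake_segmented(rep(0.1, 1200), rep(0.2, 1200),
                       labels = c("sit_to_stand", "walk1", "turn1", "walk2",
                                  "turn2", "stand_to_sit"))
  m <- extract_all(st)
  subtask_durs <- c("total_duration", "sit_to_stand_duration",
                    "walk1_duration", "turn1_duration", "walk2_duration",
                    "turn2_duration", "stand_to_sit_duration")
  expect_false(anyNA(m$value[m$measure_name %in% subtask_durs]))
  expect_true(all(is.na(
    m$value[grepl("(step_duration|regularity|symmetry)", m$measure_name)])))
  expect_true(all(m$value[grepl("step_count", m$measure_name)] == 0))
})

test_that("measures are offset-invariant except the transition median", {
  rec <- simulate_recording(group_params(), "TUG", 1, seed = 6)
  rec_off <- rec
  for (ch in c("acc_v", "acc_ml", "acc_ap"))
    rec_off[[ch]] <- rec_off[[ch]] + 0.5
  m0 <- extract_all(segment_tug(rec))
  m1 <- extract_all(segment_tug(rec_off))
  expect_identical(m0$measure_name, m1$measure_name)
  is_median <- grepl("_median_", paste0(m0$measure_name, "_"))
  same <- abs(m0$value - m1$value) < 1e-8 | (is.na(m0$value) & is.na(m1$value))
  expect_true(all(same[!is_median]))
  expect_equal(m1$value[is_median], m0$value[is_median] + 0.5,
               tolerance = 1e-8)
})

test_that("doubling the sampling rate moves every measure by < 2%", {
  p <- noiseless_params()
  m100 <- extract_all(segment_tug(simulate_recording(p, "TUG", 1, fs = 100)))
  m200 <- extract_all(segment_tug(simulate_recording(p, "TUG", 1, fs = 200)))
  expect_identical(m100$measure_name, m200$measure_name)
  a <- m100$value; b <- m200$value
  rel <- abs(a - b) / pmax(abs(a), abs(b), 1e-6)
  expect_true(all(rel < 0.02, na.rm = TRUE))
})
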
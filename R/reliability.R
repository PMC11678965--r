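# Test-retest statistics: two-way absolute-agreement single-measure ICC with
# F-based confidence interval (McGraw-Wong ICC(A,1)), SEM, MDC, relative
# change, and Bland-Altman limits of agreement with exact-t confidence
# intervals.

#' Trial matrix
#'
#' n participants x k trials of one measure. Participants with any missing
#' trial are dropped (pairwise-complete), with the drop count recorded.
#'
#' @param values numeric matrix (participants x trials) or a long data.frame
#'   with participant_id, trial, value columns.
#' @param measure_name,group_label metadata carried along.
#' @return object of class `trial_matrix`.
#' @export
trial_matrix <- function(values, measure_name = NA_character_,
                         group_label = NA_character_) {
  if (is.data.frame(values)) {
    wide <- stats::reshape(
      values[, c("participant_id", "trial", "value")],
      idvar = "participant_id", timevar = "trial", direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$participant_id
    values <- m[, order(colnames(m)), drop = FALSE]
  }
  values <- as.matrix(values)
  complete <- stats::complete.cases(values)
  dropped <- sum(!complete)
  values <- values[complete, , drop = FALSE]
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("trial_matrix: need >= 2 participants and >= 2 trials after ",
         "dropping incomplete rows")
  structure(list(values = values, measure_name = measure_name,
                 group_label = group_label, n_dropped = dropped),
            class = "trial_matrix")
}

# two-way ANOVA mean squares for a complete n x k matrix
anova_mean_squares <- function(y) {
  n <- nrow(y); k <- ncol(y)
  gm <- mean(y)
  rm_ <- rowMeans(y); cm <- colMeans(y)
  msp <- k * sum((rm_ - gm)^2) / (n - 1)
  mst <- n * sum((cm - gm)^2) / (k - 1)
  resid <- y - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  list(msp = msp, mst = mst, mse = mse, n = n, k = k)
}

#' Absolute-agreement intraclass correlation
#'
#' Single-measure two-way model with absolute agreement:
#' `ICC = (MSP - MSE) / (MSP + (k-1) MSE + (k/n)(MST - MSE))`,
#' with MSP/MST/MSE the two-way ANOVA mean squares for participants, trials
#' and error. The 95% CI uses the McGraw-Wong F-distribution interval for
#' ICC(A,1). The estimate can be negative.
#'
#' @param m a [trial_matrix()] or a plain numeric matrix.
#' @param conf confidence level.
#' @return list(icc, ci95 = c(low, high), msp, mst, mse, n, k).
#' @export
icc_agreement <- function(m, conf = 0.95) {
  y <- if (inherits(m, "trial_matrix")) m$values else as.matrix(m)
  if (nrow(y) < 2L || ncol(y) < 2L)
    stop("icc_agreement: need n >= 2 and k >= 2")
  if (anyNA(y)) stop("icc_agreement: missing values; use trial_matrix()")
  ms <- anova_mean_squares(y)
  n <- ms$n; k <- ms$k
  if (ms$msp <= 0 && ms$mst <= 0 && ms$mse <= 0)
    stop("icc_agreement: degenerate data (zero total variance)")
  denom <- ms$msp + (k - 1) * ms$mse + (k / n) * (ms$mst - ms$mse)
  icc <- if (denom == 0) 1 else (ms$msp - ms$mse) / denom
  alpha <- 1 - conf
  ci <- c(NA_real_, NA_real_)
  if (ms$mse > 0 || ms$mst > 0) {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    if (is.finite(a) && is.finite(b)) {
      v <- (a * ms$mst + b * ms$mse)^2 /
        ((a * ms$mst)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (ms$msp - fl * ms$mse) /
        (fl * (k * ms$mst + (k * n - k - n) * ms$mse) + n * ms$msp)
      hi <- n * (fu * ms$msp - ms$mse) /
        (k * ms$mst + (k * n - k - n) * ms$mse + n * fu * ms$msp)
      ci <- c(lo, hi)
    } else ci <- c(1, 1) # icc exactly 1: no uncertainty in this model
  } else ci <- c(1, 1)
  list(icc = icc, ci95 = ci, msp = ms$msp, mst = ms$mst, mse = ms$mse,
       n = n, k = k)
}

#' Standard error of measurement
#'
#' `SEM = SD * sqrt(1 - ICC)`. The conventional SD is pooled over all n x k
#' observations; a trial-1-only SD is available via `sd_value`.
#'
#' @param sd_value the SD, in measure units.
#' @param icc intraclass correlation (<= 1).
#' @return SEM in measure units.
#' @export
sem <- function(sd_value, icc) {
  if (any(icc > 1)) stop("sem: icc must be <= 1")
  sd_value * sqrt(1 - icc)
}

#' Minimal detectable change
#'
#' `MDC = SEM * 1.96 * sqrt(2)`.
#'
#' @param sem_value SEM in measure units (>= 0).
#' @return MDC in measure units.
#' @export
mdc <- function(sem_value) {
  stopifnot(all(sem_value >= 0))
  sem_value * 1.96 * sqrt(2)
}

#' Relative change between two trials
#'
#' `RC = (t2 - t1) / t1`; zero for a perfectly repeatable measurement.
#'
#' @param t1 first-trial value (> 0).
#' @param t2 second-trial value.
#' @return signed unitless relative change.
#' @export
relative_change <- function(t1, t2) {
  if (any(t1 <= 0)) stop("relative_change: first-trial value must be > 0")
  (t2 - t1) / t1
}

#' Summarize relative change across participants
#'
#' @param rc vector of per-participant relative changes.
#' @return list(median_rc, median_abs_rc, n).
#' @export
group_rc_summary <- function(rc) {
  rc <- rc[!is.na(rc)]
  if (length(rc) == 0L) stop("group_rc_summary: no values")
  list(median_rc = stats::median(rc),
       median_abs_rc = stats::median(abs(rc)),
       n = length(rc))
}

#' Bland-Altman agreement summary
#'
#' Per-participant trial differences against trial means; 95% limits of
#' agreement `bias +/- 1.96 SD(diff)`, exact-t confidence intervals on the
#' bias and on each limit (Bland-Altman 1986 variance approximation,
#' `var(LoA) ~ sd^2 (1/n + 1.96^2 / (2(n-1)))`), and the count of points
#' outside the LoA.
#'
#' @param m a [trial_matrix()] with k = 2, or an n x 2 matrix, n >= 3.
#' @return list(bias, sd_diff, loa_low, loa_high, bias_ci, loa_ci_halfwidth,
#'   n, prop_inside, n_outside).
#' @export
bland_altman <- function(m) {
  y <- if (inherits(m, "trial_matrix")) m$values else as.matrix(m)
  if (ncol(y) != 2L) stop("bland_altman: exactly 2 trials required")
  if (nrow(y) < 3L) stop("bland_altman: n >= 3 required for CIs")
  d <- y[, 2] - y[, 1]
  n <- length(d)
  bias <- mean(d)
  sdd <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * sdd
  tcrit <- stats::qt(0.975, n - 1)
  bias_ci <- bias + c(-1, 1) * tcrit * sdd / sqrt(n)
  se_loa <- sdd * sqrt(1 / n + 1.96^2 / (2 * (n - 1)))
  inside <- d >= loa[1] & d <= loa[2]
  list(bias = bias, sd_diff = sdd, loa_low = loa[1], loa_high = loa[2],
       bias_ci = bias_ci, loa_ci_halfwidth = tcrit * se_loa, n = n,
       prop_inside = mean(inside), n_outside = sum(!inside))
}

#' Qualitative ICC label
#'
#' Thresholds: < 0.5 poor, [0.5, 0.75) moderate, [0.75, 0.90] good,
#' > 0.90 excellent.
#'
#' @param icc intraclass correlation (<= 1).
#' @return one of "poor", "moderate", "good", "excellent".
#' @export
classify_icc <- function(icc) {
  stopifnot(all(icc <= 1))
  out <- character(length(icc))
  out[icc < 0.5] <- "poor"
  out[icc >= 0.5 & icc < 0.75] <- "moderate"
  out[icc >= 0.75 & icc <= 0.90] <- "good"
  out[icc > 0.90] <- "excellent"
  out
}

#' Full reliability table for a measure table
#'
#' For every (task, group, measure) cell with two trials: ICC with 95% CI and
#' label, SEM (pooled SD), MDC, median signed and absolute relative change,
#' and the Bland-Altman summary.
#'
#' @param measures long-format measure table (see [extract_all()]), two
#'   trials per participant.
#' @param sem_sd `"pooled"` (default) or `"trial1"`.
#' @return data.frame, one row per group x task x measure.
#' @export
reliability_table <- function(measures, sem_sd = c("pooled", "trial1")) {
  sem_sd <- match.arg(sem_sd)
  cells <- unique(measures[, c("group", "task", "measure_name")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- measures[measures$group == cells$group[i] &
                      measures$task == cells$task[i] &
                      measures$measure_name == cells$measure_name[i], ]
    tm <- tryCatch(trial_matrix(sub, cells$measure_name[i], cells$group[i]),
                   error = function(e) NULL)
    if (is.null(tm)) next
    res <- tryCatch(icc_agreement(tm), error = function(e) NULL)
    if (is.null(res)) next
    y <- tm$values
    sd_val <- if (sem_sd == "pooled") stats::sd(as.vector(y)) else
      stats::sd(y[, 1])
    sem_val <- sem(sd_val, min(res$icc, 1))
    rc <- if (all(y[, 1] > 0)) (y[, 2] - y[, 1]) / y[, 1] else
      rep(NA_real_, nrow(y))
    rcs <- if (all(is.na(rc))) list(median_rc = NA_real_,
                                    median_abs_rc = NA_real_) else
      group_rc_summary(rc)
    ba <- tryCatch(bland_altman(tm), error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      group = cells$group[i], task = cells$task[i],
      measure = cells$measure_name[i],
      icc = res$icc, ci_low = res$ci95[1], ci_high = res$ci95[2],
      label = classify_icc(min(res$icc, 1)),
      sem = sem_val, mdc = mdc(sem_val),
      median_rc = rcs$median_rc, median_abs_rc = rcs$median_abs_rc,
      ba_bias = if (is.null(ba)) NA_real_ else ba$bias,
      ba_loa_low = if (is.null(ba)) NA_real_ else ba$loa_low,
      ba_loa_high = if (is.null(ba)) NA_real_ else ba$loa_high,
      n_used = nrow(y), n_dropped = tm$n_dropped,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
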
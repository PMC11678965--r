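#' @useDynLib mobilitytrt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Cumulative trapezoidal integration
#'
#' Integrates a sampled series with the trapezoid rule, returning the running
#' integral. Used to convert yaw angular velocity (degrees/s) into angular
#' position (degrees).
#'
#' @param x numeric series (length >= 2).
#' @param fs sampling rate in Hz.
#' @return numeric vector, same length as `x`, first element 0.
#' @keywords internal
cumtrapz <- function(x, fs) {
  if (length(x) < 2) stop("cumtrapz: series must have length >= 2")
  dt <- 1 / fs
  c(0, cumsum((x[-1] + x[-length(x)]) / 2 * dt))
}

#' Centered moving average
#'
#' @param x numeric series.
#' @param win window length in samples (coerced odd, >= 1).
#' @return smoothed series, same length; edges use the available window.
#' @keywords internal
moving_average <- function(x, win) {
  win <- max(1L, as.integer(win))
  if (win %% 2L == 0L) win <- win + 1L
  if (win == 1L) return(x)
  n <- length(x)
  half <- (win - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Rolling RMS over a centered window; the oscillation envelope used by the
# walk-onset detector.
rolling_rms <- function(x, win) {
  sqrt(pmax(moving_average(x^2, win), 0))
}

#' Find peaks in a series
#'
#' Local maxima filtered by a minimum inter-peak distance and a minimum
#' prominence, the convention used for step detection throughout the package.
#' When two candidate peaks are closer than `min_dist`, the taller one wins.
#'
#' @param x numeric series.
#' @param min_dist minimum distance between retained peaks, in samples.
#' @param min_prominence minimum topographic prominence; peaks below are
#'   discarded.
#' @return integer vector of peak indices (1-based), increasing.
#' @export
find_peaks <- function(x, min_dist = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))
  if (min_prominence > 0) {
    keep <- vapply(cand, function(i) {
      peak_prominence(x, i, cand) >= min_prominence
    }, logical(1))
    cand <- cand[keep]
    if (length(cand) == 0L) return(integer(0))
  }
  if (min_dist > 1L && length(cand) > 1L) {
    ord <- cand[order(x[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord) {
      if (all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  cand
}

# Topographic prominence of peak i: height above the higher of the two saddle
# minima found walking out to the nearest strictly taller sample on each side
# (or the series end).
peak_prominence <- function(x, i, peaks = NULL) {
  n <- length(x)
  h <- x[i]
  left <- if (i > 1L) {
    taller <- which(x[1:(i - 1L)] > h)
    lo <- if (length(taller)) max(taller) + 1L else 1L
    min(x[lo:i])
  } else h
  right <- if (i < n) {
    taller <- which(x[(i + 1L):n] > h)
    hi <- if (length(taller)) i + min(taller) - 1L else n
    min(x[i:hi])
  } else h
  h - max(left, right)
}

#' Unbiased normalized autocorrelation
#'
#' Mean-removed autocorrelation with the unbiased estimator (sum divided by
#' N - lag), normalized by the lag-0 value so that values are comparable to a
#' correlation. The estimate is clipped to [-1, 1]; the unbiased estimator can
#' slightly exceed 1 at large lags.
#'
#' @param x numeric series.
#' @param max_lag largest lag in samples.
#' @return numeric vector of length `max_lag + 1`, autocorrelation at lags
#'   `0:max_lag`.
#' @export
autocorr_unbiased <- function(x, max_lag) {
  n <- length(x)
  max_lag <- min(as.integer(max_lag), n - 1L)
  x <- x - mean(x)
  denom <- sum(x^2) / n
  if (denom <= 0) return(rep(NA_real_, max_lag + 1L))
  r <- vapply(0:max_lag, function(l) {
    sum(x[1:(n - l)] * x[(1 + l):n]) / (n - l)
  }, numeric(1))
  pmin(pmax(r / denom, -1), 1)
}

#' Welch power spectral density estimate
#'
#' Hann-tapered, overlapped segment averaging with 50% overlap. The default
#' segment length is 2.56 s of signal (256 samples at the canonical 100 Hz
#' sampling rate), expressed in time rather than samples so that spectral
#' resolution - and hence the PSD peak amplitude and width - does not depend
#' on the sampling rate. The series mean is removed before windowing.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param nperseg segment length in samples.
#' @param overlap fractional overlap between segments in [0, 1).
#' @return list with `freq` (Hz) and `psd` (power per Hz) for the one-sided
#'   spectrum.
#' @export
welch_psd <- function(x, fs, nperseg = min(length(x), round(2.56 * fs)),
                      overlap = 0.5) {
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  if (nperseg < 8L) stop("welch_psd: series too short")
  x <- x - mean(x)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / (nperseg + 1)))
  u <- sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[1:nfreq])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * u * fs)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  if (nperseg %% 2L == 0L) {
    psd[2:(nfreq - 1L)] <- 2 * psd[2:(nfreq - 1L)]
  } else if (nfreq > 1L) {
    psd[2:nfreq] <- 2 * psd[2:nfreq]
  }
  list(freq = (0:(nfreq - 1L)) * fs / nperseg, psd = psd)
}
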
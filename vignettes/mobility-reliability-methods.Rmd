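---
title: "Methods: test-retest reliability of instrumented mobility tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: test-retest reliability of instrumented mobility tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`mobilitytrt` implements a complete, testable pipeline for studying the
test-retest reliability of three instrumented mobility tasks commonly used in
Parkinson's disease (PD) assessment: the Timed Up and Go (TUG), the TUG with
a concurrent serial-subtraction task (cogTUG), and a 32-foot walk containing
three ~180-degree turns that is analyzed as two back-to-back 16-foot trials.
Because real cohort recordings cannot be redistributed, the package's first
module is a synthetic-data generator with exported ground truth; every
downstream stage (segmentation, measure extraction, agreement statistics,
diagnostic modelling) is exercised against that stated world.

## The measurement model

All reliability statistics are built on the two-way decomposition of a
participants-by-trials measurement table,

$$Y_{ij} = \mu + p_i + t_j + e_{ij},$$

with participant effects $p_i \sim N(0, \sigma_p^2)$, fixed trial offsets of
scale $\sigma_t$, and residuals $e_{ij} \sim N(0, \sigma_e^2)$. The
agreement intraclass correlation is the single-measure two-way
absolute-agreement form,

$$\mathrm{ICC} = \frac{MS_P - MS_E}
{MS_P + (k-1) MS_E + \tfrac{k}{n}(MS_T - MS_E)},$$

where $MS_P$, $MS_T$ and $MS_E$ are the ANOVA mean squares for participants,
trials and error. With $\sigma_t = 0$ the expected ICC is
$\sigma_p^2 / (\sigma_p^2 + \sigma_e^2)$, which is how
`simulate_measure_table()` doubles as a parameter-recovery oracle: the
generator is the model. Derived statistics follow their standard
definitions: $\mathrm{SEM} = SD\sqrt{1-\mathrm{ICC}}$,
$\mathrm{MDC} = \mathrm{SEM} \times 1.96 \times \sqrt{2}$, relative change
$\mathrm{RC} = (Y_{i2} - Y_{i1})/Y_{i1}$, and Bland-Altman 95% limits of
agreement $\bar d \pm 1.96\, SD_d$.

Two genuinely open choices were resolved as follows:

* **ICC confidence interval.** No CI method is prescribed by the formula
  alone; we use the F-distribution interval for the McGraw-Wong ICC(A,1)
  coefficient, the form that matches the point-estimate formula. It agrees
  with `pingouin.intraclass_corr`'s ICC2 row.
* **SD in the SEM.** "SD" is ambiguous between the pooled SD over all
  $n \times k$ observations and the trial-1 SD. Pooled is the default;
  `reliability_table(sem_sd = "trial1")` selects the alternative.
* **ICC labels.** Thresholds 0.5 / 0.75 / 0.90 with left-closed bands:
  ICC = 0.90 is still "good", anything above is "excellent". The verbal
  convention overlaps at 0.90, so the boundary is fixed here and tested.

## The synthetic world

`simulate_recording()` builds a six-axis 100 Hz recording from a segment
plan (sit-to-stand, walk, turn, walk, turn, stand-to-sit for TUG/cogTUG;
four walks and three turns for the 32-foot task). Its components:

* **Gait** is a train of one-per-step unimodal pulses (a raised-cosine
  fundamental at the step rate plus a 15% second harmonic, kept below the
  unimodality limit), with per-step timing jitter (`step_frequency_cv`),
  per-step amplitude jitter, and an alternate-step amplitude ratio
  (`asymmetry_ratio`) that makes step-versus-stride autocorrelation
  structure controllable. Vertical amplitude is 0.25 g, anteroposterior
  0.6 of that - representative of lower-back accelerometry during
  comfortable walking.
* **Turns** are raised-cosine yaw-velocity pulses whose trapezoidal
  integral is exactly 180 degrees, so turn-angle recovery has an analytic
  truth. Stepping continues through turns at 0.7 amplitude.
* **Chair transitions** are single low-frequency raised-cosine lobes on the
  anteroposterior (0.5 g) and vertical (0.4 g) channels.
* **Groups.** Four profiles (control / mild / moderate / severe) scale
  durations, timing variability, asymmetry, the between-subject speed SD
  and the trial-2 duration multiplier. Values are package choices tuned to
  be physiologically plausible (e.g. a 12 s control TUG), not estimates
  from any cohort. Severity couples a large between-subject SD
  (`0.35` on the log scale) with a strong learning effect
  (`trial2_multiplier = 0.85`); that pairing is what produces the
  high-ICC / high-|RC| configuration the paradox analysis flags.
* **Trial effects.** TUG/cogTUG trials are separated by a rest, so the
  second trial is faster (learning, multiplier < 1). The two 16-foot
  trials are halves of one continuous recording, so the second half is
  slower (fatigue); one multiplier cannot express both signs, hence the
  separate `walk32_trial2_multiplier` (> 1).

Each participant draws a single log-normal speed offset
(`exp(N(0, between_subject_sd^2))`) shared across trials and tasks; this is
the sole source of between-subject variance and hence of nonzero downstream
ICC.

What the generator does **not** emulate: biomechanically realistic limb
kinematics, freezing-of-gait, sensor drift or re-positioning error,
day-to-day physiological variation, or missing-data patterns of real
devices. A green pipeline test therefore establishes algorithmic
correctness on signals with known structure - not clinical validity on
patient data.

## Segmentation choices

* Intervals are 0-based half-open `[start, end)` sample ranges, so
  durations add exactly and adjacent segments tile the recording.
* **Turn detection** integrates yaw velocity (trapezoid rule), smooths with
  a 0.25 s moving average, and takes maximal intervals of consistent
  rotation with net change >= 90 degrees (`min_angle_deg`; protocol turns
  are ~180 degrees, gait sway is far below 90). Boundaries are trimmed to
  the 5%/95% quantiles of the net angular change, then extended to the
  nearest near-zero of the smoothed yaw velocity. The upstream algorithm's
  exact thresholds are not public; these stand-ins are configurable and
  validated against generator truth (boundaries within 0.25 s on noiseless
  input).
* **Walking onset** (end of sit-to-stand) uses the envelope (0.25 s rolling
  RMS) of the high-passed vertical acceleration (signal minus its 0.6 s
  moving average; the moving-average notch separates the ~0.4-0.7 Hz
  transition lobe from the ~2 Hz step oscillation). Onset is the first
  sample where the envelope exceeds
  `max(3 x leading-baseline SD, 0.4 x 90th percentile)` for at least
  0.5 s. A pure seated-baseline criterion was not possible because the
  analyzed recording begins at the sit-to-stand onset; the hybrid threshold
  is documented here and configurable in `detect_walk_onset()`.
* The 32-foot task is split by omitting the middle turn entirely: trial 1
  ends at its onset, trial 2 starts at its end.

## Measure definitions

Step counting uses peak detection with a 0.3 s minimum inter-peak distance
(cadence up to ~3.3 steps/s) and prominence at least half the segment SD.
Regularity uses the unbiased autocorrelation (sum divided by $N - \ell$)
normalized at lag 0, with the peak search restricted to lags 0.2-2.5 s;
step regularity is the first dominant peak, stride regularity the second,
and step symmetry is `min(r, 1/r)` of their ratio - symmetric in its
arguments, bounded in (0, 1], monotone in proximity to 1. The Welch PSD
uses Hann tapers and 50% overlap with a default segment length of 2.56 s
(256 samples at 100 Hz); the length is expressed in time rather than
samples so that spectral resolution, and with it the PSD peak amplitude and
width, is invariant to the sampling rate - this keeps the module's
sampling-invariance property (< 2% change when `fs` doubles) true for
every measure. Jerk is the RMS of the finite-difference derivative. The
exact published measure enumeration (77 per TUG trial) lives in an
unavailable appendix; the schema here implements every named measure
family (65 measures per TUG trial, 43 per 16-foot trial) and is
deliberately configurable rather than a count-for-count reproduction.
Undefined measures (too few steps, nonpositive stride regularity) are
explicit `NA`s, never silent zeros.

## Diagnostic modelling

The classifier protocol is: five replicates of stratified five-fold
cross-validation (replicate $r$ reseeds at `seed + r`); within each
training fold, random-forest importance ranking, elbow-point cutoff (the
point farthest from the chord joining the first and last importance
values; ties, including collinear curves, resolve to the first index), and
forward selection over cumulative top-ranked subsets scored by
$AIC_j = 2j - 2\ln\hat L_j$; then majority-class undersampling to the
minority size and a final forest (default 10,000 trees; tests use 500,
which is inside cross-validation noise). Each participant accrues one
vote per replicate; the final class is the majority of five (a tie is
impossible with five binary votes; for even configurations it falls to the
positive class by documented rule).

Two definitional gaps were closed as package choices:

* **A forest has no likelihood.** $\hat L_j$ uses out-of-bag predicted
  probabilities of each sample's true class, clipped to
  $[10^{-6}, 1-10^{-6}]$, with $j$ (the number of features) as the
  parameter count. The surrogate is seeded, documented and swappable.
* **No forest package exists in the target environment**, so the package
  ships its own seeded CART forest (Gini splits, `floor(sqrt(p))` features
  per node, bootstrap resampling) in C++; it draws from R's RNG stream so
  `set.seed()` governs it exactly like base R code.

The duration-only benchmark runs the identical cross-validation,
undersampling and voting protocol with logistic regression on a single
predictor (mean total duration over both trials), isolating the
informational value of the sensor-derived measures from the protocol
itself.

## Numerical and degenerate-input policy

Zero-variance trial matrices raise a degenerate-data error rather than
returning an ICC; perfect agreement returns exactly 1. Participants
missing either trial are dropped per measure with counts reported.
Segmentation failures (wrong turn count) abort only the affected
recording: cohort-level functions log and skip. The unbiased
autocorrelation can exceed 1 at high lags; values are clipped to
[-1, 1]. Elbow and AIC ties resolve to the smallest index/subset
(parsimony, determinism).

## Known limitations

The generator's parameter defaults are stated choices, not fitted values;
absolute ICCs or model accuracies from the synthetic cohort are not
comparable to any real cohort's values. The 16-foot "trials" inherit the
limitation of being halves of one recording. MDC estimates from
back-to-back trials understate day-to-day measurement error by design.
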
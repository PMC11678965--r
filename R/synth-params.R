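#' Group simulation parameters
#'
#' Bundle of generator knobs describing one participant group. Durations are
#' seconds, accelerations g, angular velocities degrees/s. `step_frequency_hz`
#' is the stride rate (cadence / 2); vertical acceleration oscillates at twice
#' this value, once per step.
#'
#' @param group_label one of `"control"`, `"mild"`, `"moderate"`, `"severe"`.
#' @param step_frequency_hz mean stride rate in Hz, in (0.5, 3).
#' @param step_frequency_cv within-walk coefficient of variation of step
#'   timing (unitless).
#' @param walk_speed_scale multiplier on nominal segment durations (> 1 means
#'   slower).
#' @param turn_duration_s nominal duration of a 180 degree turn.
#' @param transition_duration_s nominal sit-to-stand / stand-to-sit duration.
#' @param noise_sd_g accelerometer white-noise SD (g).
#' @param between_subject_sd SD of the per-participant log speed offset; a
#'   participant's durations are scaled by `exp(N(0, between_subject_sd^2))`,
#'   drawn once and shared across trials and tasks.
#' @param trial2_multiplier duration multiplier for the second TUG/cogTUG
#'   trial (< 1 = learning effect, > 1 = fatigue).
#' @param walk32_trial2_multiplier duration multiplier for the second half of
#'   the 32-foot walk (its two 16-foot trials are back-to-back, so fatigue,
#'   not learning, is typical: default slightly > 1).
#' @param asymmetry_ratio amplitude ratio of alternate steps in (0, 1];
#'   1 = symmetric gait.
#' @param amplitude_jitter per-step relative amplitude jitter SD.
#' @param gyro_noise_sd_dps gyroscope white-noise SD (degrees/s).
#' @param base_walk_s nominal duration of one 8-foot walk bout at
#'   `walk_speed_scale = 1`.
#' @param cogtug_scale extra duration multiplier applied to cogTUG (dual-task
#'   slowing).
#' @return object of class `group_params`.
#' @export
group_params <- function(group_label = "control",
                         step_frequency_hz = 1.0,
                         step_frequency_cv = 0.04,
                         walk_speed_scale = 1.0,
                         turn_duration_s = 2.0,
                         transition_duration_s = 1.5,
                         noise_sd_g = 0.02,
                         between_subject_sd = 0.08,
                         trial2_multiplier = 0.98,
                         walk32_trial2_multiplier = 1.03,
                         asymmetry_ratio = 1.0,
                         amplitude_jitter = 0.05,
                         gyro_noise_sd_dps = 2.0,
                         base_walk_s = 2.5,
                         cogtug_scale = 1.15) {
  p <- list(
    group_label = group_label,
    step_frequency_hz = step_frequency_hz,
    step_frequency_cv = step_frequency_cv,
    walk_speed_scale = walk_speed_scale,
    turn_duration_s = turn_duration_s,
    transition_duration_s = transition_duration_s,
    noise_sd_g = noise_sd_g,
    between_subject_sd = between_subject_sd,
    trial2_multiplier = trial2_multiplier,
    walk32_trial2_multiplier = walk32_trial2_multiplier,
    asymmetry_ratio = asymmetry_ratio,
    amplitude_jitter = amplitude_jitter,
    gyro_noise_sd_dps = gyro_noise_sd_dps,
    base_walk_s = base_walk_s,
    cogtug_scale = cogtug_scale
  )
  class(p) <- "group_params"
  validate_group_params(p)
  p
}

validate_group_params <- function(p) {
  stopifnot(
    p$step_frequency_hz > 0.5, p$step_frequency_hz < 3,
    p$step_frequency_cv >= 0,
    p$walk_speed_scale > 0,
    p$turn_duration_s > 0,
    p$transition_duration_s > 0,
    p$noise_sd_g >= 0,
    p$between_subject_sd >= 0,
    p$trial2_multiplier > 0,
    p$walk32_trial2_multiplier > 0,
    p$asymmetry_ratio > 0, p$asymmetry_ratio <= 1,
    p$base_walk_s > 0
  )
  invisible(p)
}

#' Default group profiles
#'
#' Four named profiles (control, mild, moderate, severe) loaded from the
#' package's YAML config (`inst/extdata/group_profiles.yaml`). Severity
#' increases nominal durations, timing variability, gait asymmetry and,
#' most importantly for the reliability analysis, the between-subject speed
#' SD and the distance of the trial-2 multiplier from 1: the severe profile
#' couples a large between-subject SD with a 0.85 trial-2 multiplier, which
#' reproduces the high-ICC / high-relative-change paradox.
#'
#' @param path optional path to an alternative YAML profile file.
#' @return named list of `group_params`.
#' @export
default_group_profiles <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "group_profiles.yaml",
                        package = "mobilitytrt")
  }
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw$groups), function(nm) {
    do.call(group_params, c(list(group_label = nm), raw$groups[[nm]]))
  })
  names(out) <- names(raw$groups)
  out
}

#' Variance components for the two-trial measurement model
#'
#' Generative counterpart of the two-way ANOVA decomposition behind the
#' agreement ICC: `Y_ij = mu + p_i + t_j + e_ij` with participant effects
#' `p_i ~ N(0, sigma_p^2)`, fixed trial offsets of scale `sigma_t`, and
#' residuals `e_ij ~ N(0, sigma_e^2)`.
#'
#' @param mu grand mean, in measure units.
#' @param sigma_p between-participant SD.
#' @param sigma_t between-trial (systematic) effect scale.
#' @param sigma_e residual SD.
#' @return object of class `variance_components`.
#' @export
variance_components <- function(mu = 0, sigma_p = 1, sigma_t = 0,
                                sigma_e = 1) {
  stopifnot(sigma_p >= 0, sigma_t >= 0, sigma_e >= 0)
  structure(list(mu = mu, sigma_p = sigma_p, sigma_t = sigma_t,
                 sigma_e = sigma_e),
            class = "variance_components")
}
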
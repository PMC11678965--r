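# Default simulation profiles for the four participant groups.
# Durations in seconds, accelerations in g, angular velocity in degrees/s.
# Severity slows movement (walk_speed_scale), lengthens turns/transitions,
# increases timing variability and asymmetry, and widens the between-subject
# speed distribution. trial2_multiplier < 1 encodes the TUG/cogTUG learning
# effect; walk32_trial2_multiplier > 1 encodes the back-to-back 16-foot walk
# fatigue effect.
groups:
  control:
    step_frequency_hz: 1.00
    step_frequency_cv: 0.04
    walk_speed_scale: 1.00
    turn_duration_s: 2.0
    transition_duration_s: 1.5
    noise_sd_g: 0.02
    between_subject_sd: 0.08
    trial2_multiplier: 0.98
    walk32_trial2_multiplier: 1.02
    asymmetry_ratio: 1.00
    amplitude_jitter: 0.05
  mild:
    step_frequency_hz: 0.95
    step_frequency_cv: 0.06
    walk_speed_scale: 1.15
    turn_duration_s: 2.3
    transition_duration_s: 1.8
    noise_sd_g: 0.02
    between_subject_sd: 0.12
    trial2_multiplier: 0.97
    walk32_trial2_multiplier: 1.03
    asymmetry_ratio: 0.95
    amplitude_jitter: 0.06
  moderate:
    step_frequency_hz: 0.90
    step_frequency_cv: 0.09
    walk_speed_scale: 1.40
    turn_duration_s: 2.8
    transition_duration_s: 2.2
    noise_sd_g: 0.02
    between_subject_sd: 0.18
    trial2_multiplier: 0.95
    walk32_trial2_multiplier: 1.04
    asymmetry_ratio: 0.90
    amplitude_jitter: 0.08
  severe:
    step_frequency_hz: 0.85
    step_frequency_cv: 0.13
    walk_speed_scale: 2.00
    turn_duration_s: 3.5
    transition_duration_s: 2.8
    noise_sd_g: 0.02
    between_subject_sd: 0.35
    trial2_multiplier: 0.85
    walk32_trial2_multiplier: 1.06
    asymmetry_ratio: 0.80
    amplitude_jitter: 0.10
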
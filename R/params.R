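#' Beat morphology parameters for the PPG simulator
#'
#' Bundles the generative parameters of one subject's pulse waveform: heart
#' rate and beat-to-beat interval variability, the systolic wave width and
#' amplitude, the reflected (P2) wave amplitude and delay, the dicrotic-notch
#' depth, and baseline drift / additive noise levels.
#'
#' @param heart_rate_bpm Mean pulse rate in beats per minute (30--200).
#' @param ibi_sd_ms Beat-to-beat interval standard deviation in milliseconds.
#' @param sys_width_s Width (Gaussian SD, seconds) of the systolic upstroke;
#'   the diastolic runoff time constant is tied to this value, so it is the
#'   single knob controlling waveform sharpness.
#' @param sys_amp Systolic peak amplitude, arbitrary units.
#' @param refl_amp_frac Reflected-wave amplitude as a fraction of `sys_amp`
#'   (0--1, exclusive of 1).
#' @param refl_delay_s Delay of the reflected peak after the systolic peak in
#'   seconds; maps onto the peak time difference between the systolic and
#'   diastolic peaks. Must be shorter than one mean beat.
#' @param notch_depth_frac Dicrotic-notch depth as a fraction of the local
#'   waveform envelope at the notch (0--1).
#' @param drift_amp Amplitude of the sinusoidal baseline drift (same units as
#'   `sys_amp`).
#' @param drift_freq_hz Baseline drift frequency, below 0.3 Hz.
#' @param noise_sd Additive white-noise SD.
#' @param ibi_mod_freq_hz Optional sinusoidal modulation frequency of the
#'   beat-to-beat intervals (Hz); gives the interval series a narrowband
#'   component so pulse-rate-variability spectra have localized power.
#' @param ibi_mod_depth_ms Peak amplitude of that interval modulation (ms).
#'
#' @return An object of class `morph_params` (a named list).
#' @examples
#' p <- morph_params(heart_rate_bpm = 75)
#' p$sys_width_s
#' @export
morph_params <- function(heart_rate_bpm = 75,
                         ibi_sd_ms = 25,
                         sys_width_s = 0.037,
                         sys_amp = 450,
                         refl_amp_frac = 0.45,
                         refl_delay_s = 0.43,
                         notch_depth_frac = 0.5,
                         drift_amp = 0,
                         drift_freq_hz = 0.1,
                         noise_sd = 0,
                         ibi_mod_freq_hz = 0,
                         ibi_mod_depth_ms = 0) {
  check_number(heart_rate_bpm, "heart_rate_bpm", 30, 200)
  check_number(ibi_sd_ms, "ibi_sd_ms", 0)
  check_number(sys_width_s, "sys_width_s", 0, strict_lower = TRUE)
  check_number(sys_amp, "sys_amp", 0, strict_lower = TRUE)
  check_number(refl_amp_frac, "refl_amp_frac", 0, 1, strict_upper = TRUE)
  check_number(refl_delay_s, "refl_delay_s", 0, strict_lower = TRUE)
  check_number(notch_depth_frac, "notch_depth_frac", 0, 1)
  check_number(drift_amp, "drift_amp", 0)
  check_number(drift_freq_hz, "drift_freq_hz", 0, 0.3, strict_upper = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  check_number(ibi_mod_freq_hz, "ibi_mod_freq_hz", 0)
  check_number(ibi_mod_depth_ms, "ibi_mod_depth_ms", 0)
  if (refl_delay_s >= 60 / heart_rate_bpm) {
    abort("`refl_delay_s` must be shorter than the mean beat (60 / heart_rate_bpm).")
  }
  structure(
    list(
      heart_rate_bpm = heart_rate_bpm, ibi_sd_ms = ibi_sd_ms,
      sys_width_s = sys_width_s, sys_amp = sys_amp,
      refl_amp_frac = refl_amp_frac, refl_delay_s = refl_delay_s,
      notch_depth_frac = notch_depth_frac,
      drift_amp = drift_amp, drift_freq_hz = drift_freq_hz,
      noise_sd = noise_sd,
      ibi_mod_freq_hz = ibi_mod_freq_hz, ibi_mod_depth_ms = ibi_mod_depth_ms
    ),
    class = "morph_params"
  )
}

#' Per-group simulator profile
#'
#' One systolic-blood-pressure group of the synthetic cohort: the SBP
#' sampling distribution (truncated to the group's clinical interval) and the
#' group-mean morphology with per-field between-subject coefficients of
#' variation.
#'
#' @param group_id Integer 1--4 (1 = SBP <= 120 mmHg ... 4 = SBP >= 160 mmHg).
#' @param sbp_mean,sbp_sd Normal parameters of the group's SBP draw (mmHg);
#'   draws are resampled until they fall inside the group interval.
#' @param params_mean A [morph_params()] object with the group-mean waveform.
#' @param params_cv Named numeric vector of coefficients of variation for the
#'   between-subject log-normal draws; names must be `morph_params` fields.
#'   Fields not named get CV 0 (no between-subject spread).
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(group_id, sbp_mean, sbp_sd, params_mean,
                          params_cv = numeric()) {
  stopifnot(inherits(params_mean, "morph_params"))
  group_id <- as.integer(group_id)
  if (!group_id %in% 1:4) abort("`group_id` must be 1, 2, 3 or 4.")
  check_number(sbp_mean, "sbp_mean", 50, 300)
  check_number(sbp_sd, "sbp_sd", 0, strict_lower = TRUE)
  if (length(params_cv)) {
    bad <- setdiff(names(params_cv), names(params_mean))
    if (length(bad)) {
      abort(sprintf("Unknown `params_cv` field(s): %s", paste(bad, collapse = ", ")))
    }
    if (any(params_cv < 0)) abort("`params_cv` entries must be >= 0.")
  }
  structure(
    list(group_id = group_id, sbp_mean = sbp_mean, sbp_sd = sbp_sd,
         params_mean = params_mean, params_cv = params_cv),
    class = "group_profile"
  )
}

#' Default four-group cohort profiles
#'
#' The shipped profiles encode the group-trend directions of the study
#' conditions: with rising SBP group, the systolic width (hence every
#' sharpness index and the systolic duration) increases, the reflected-wave
#' delay shortens, the reflected-wave fraction and the interval variability
#' grow, and the systolic amplitude rises. Values are anchored to the
#' printed group means where a direct mapping exists (reflected-wave delay,
#' systolic amplitude, interval SD backed out of RMSSD/sqrt(2)).
#'
#' @return A list of four [group_profile()] objects.
#' @export
default_profiles <- function() {
  sys_width <- c(0.034, 0.037, 0.040, 0.043)
  refl_delay <- c(0.470, 0.440, 0.410, 0.380)
  refl_amp <- c(0.43, 0.44, 0.45, 0.46)
  sys_amp <- c(355, 450, 510, 540)
  ibi_sd <- c(22, 27, 30, 31)
  sbp_mean <- c(110, 130, 150, 170)
  sbp_sd <- c(8, 5, 5.5, 9)
  cv <- c(
    heart_rate_bpm = 0.02, ibi_sd_ms = 0.25, sys_width_s = 0.12,
    sys_amp = 0.45, refl_amp_frac = 0.08, refl_delay_s = 0.08,
    notch_depth_frac = 0.15, drift_amp = 0.30, noise_sd = 0.20
  )
  lapply(1:4, function(g) {
    group_profile(
      group_id = g, sbp_mean = sbp_mean[g], sbp_sd = sbp_sd[g],
      params_mean = morph_params(
        heart_rate_bpm = 75, ibi_sd_ms = ibi_sd[g],
        sys_width_s = sys_width[g], sys_amp = sys_amp[g],
        refl_amp_frac = refl_amp[g], refl_delay_s = refl_delay[g],
        notch_depth_frac = 0.5, drift_amp = 40, drift_freq_hz = 0.1,
        noise_sd = 4
      ),
      params_cv = cv
    )
  })
}

#' Null cohort profiles (no group differences in morphology)
#'
#' All four groups share one set of waveform parameters (the second group's
#' defaults) and differ only in their SBP sampling interval — the negative
#' control for the group-comparison pipeline: no feature should separate the
#' groups beyond chance.
#'
#' @return A list of four [group_profile()] objects.
#' @export
null_profiles <- function() {
  base <- default_profiles()
  ref <- base[[2]]
  lapply(base, function(p) {
    p$params_mean <- ref$params_mean
    p$params_cv <- ref$params_cv
    p
  })
}

#' Cohort simulation specification
#'
#' @param n_per_group Subjects per SBP group (>= 2).
#' @param duration_s Recording length in seconds (default 90).
#' @param fs_hz Sampling rate in Hz (default 500).
#' @param seed Integer RNG seed; the whole cohort is reproducible from it.
#' @param profiles List of exactly four [group_profile()]s with distinct
#'   `group_id`s 1--4. Defaults to [default_profiles()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group, duration_s = 90, fs_hz = 500,
                        seed = 1L, profiles = default_profiles()) {
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 2L) {
    abort("`n_per_group` must be an integer >= 2 (group statistics are undefined below that).")
  }
  check_number(duration_s, "duration_s", 0, strict_lower = TRUE)
  check_number(fs_hz, "fs_hz", 0, strict_lower = TRUE)
  seed <- as.integer(seed)
  if (length(profiles) != 4L ||
      !all(vapply(profiles, inherits, logical(1), "group_profile"))) {
    abort("`profiles` must be a list of four `group_profile` objects.")
  }
  ids <- vapply(profiles, `[[`, integer(1), "group_id")
  if (!setequal(ids, 1:4)) abort("`profiles` must carry distinct group_ids 1:4.")
  structure(
    list(n_per_group = n_per_group, duration_s = duration_s, fs_hz = fs_hz,
         seed = seed, profiles = profiles[order(ids)]),
    class = "cohort_spec"
  )
}
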
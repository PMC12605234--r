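# --- beat template ----------------------------------------------------------
#
# One valley-to-valley pulse: a Gaussian systolic upstroke that hands over
# (value- and slope-continuously) to an exponential diastolic runoff, a
# reflected Gaussian wave riding on that runoff, and a dicrotic notch carved
# out as a Gaussian dip whose amplitude is a fraction of the local envelope.
# The runoff time constant is tied to the systolic width so a single
# parameter controls waveform sharpness, and the notch always stays above
# the end-diastolic valley.

template_pieces <- function(params, beat_duration_s) {
  sigma <- params$sys_width_s
  d <- beat_duration_s
  t1 <- min(3.5 * sigma, 0.4 * d)            # onset -> systolic peak
  tau <- 5 * sigma                            # diastolic runoff constant
  delta <- min(params$refl_delay_s, 0.75 * (d - t1))
  t2 <- t1 + delta                            # reflected peak centre
  tn <- t1 + 0.70 * delta                     # notch centre, shortly before P2
  # broad reflected hump: concentrates its energy at low harmonics so the
  # upper harmonic ratios stay systolic-width-driven
  sigma_r <- max(0.22 * delta, 0.02)
  sigma_n <- max(0.05 * delta, 0.010)
  ustar <- sigma^2 / tau                      # Gaussian-to-exponential handover
  list(sigma = sigma, d = d, t1 = t1, tau = tau, t2 = t2, tn = tn,
       sigma_r = sigma_r, sigma_n = sigma_n, ustar = ustar,
       refl_amp = params$refl_amp_frac, notch_depth = params$notch_depth_frac)
}

template_systolic <- function(t, pc) {
  u <- t - pc$t1
  out <- exp(-u^2 / (2 * pc$sigma^2))
  tail_part <- u > pc$ustar
  out[tail_part] <- exp(-pc$ustar^2 / (2 * pc$sigma^2)) *
    exp(-(u[tail_part] - pc$ustar) / pc$tau)
  out
}

template_base <- function(t, pc) {
  template_systolic(t, pc) +
    pc$refl_amp * exp(-(t - pc$t2)^2 / (2 * pc$sigma_r^2))
}

template_eval <- function(t, pc) {
  notch_amp <- pc$notch_depth * template_base(pc$tn, pc)
  template_base(t, pc) - notch_amp * exp(-(t - pc$tn)^2 / (2 * pc$sigma_n^2))
}

#' Generate one sampled PPG beat
#'
#' Evaluates the pulse template for a single valley-to-valley beat and scales
#' it so the systolic maximum equals `params$sys_amp`.
#'
#' @param params A [morph_params()] object.
#' @param beat_duration_s Beat length in seconds.
#' @param fs_hz Sampling rate in Hz.
#' @return Numeric vector of `round(beat_duration_s * fs_hz)` samples starting
#'   at the onset valley; the true systolic peak index is attached as
#'   attribute `peak_idx`.
#' @examples
#' y <- simulate_beat_template(morph_params(), 0.8, 500)
#' which.max(y) == attr(y, "peak_idx")
#' @export
simulate_beat_template <- function(params, beat_duration_s, fs_hz) {
  stopifnot(inherits(params, "morph_params"))
  check_number(beat_duration_s, "beat_duration_s", 0, strict_lower = TRUE)
  check_number(fs_hz, "fs_hz", 0, strict_lower = TRUE)
  n <- max(2L, round(beat_duration_s * fs_hz))
  t <- (seq_len(n) - 1) / fs_hz
  pc <- template_pieces(params, beat_duration_s)
  y <- template_eval(t, pc)
  y <- y * params$sys_amp / max(y)
  attr(y, "peak_idx") <- which.max(y)
  y
}

# --- recording --------------------------------------------------------------

draw_ibis <- function(params, duration_s) {
  base <- 60 / params$heart_rate_bpm
  sd_s <- params$ibi_sd_ms / 1000
  n_max <- ceiling(duration_s / max(0.25, base - 3 * sd_s)) + 3L
  ib <- base + sd_s * rtnorm3(n_max)
  if (params$ibi_mod_depth_ms > 0 && params$ibi_mod_freq_hz > 0) {
    # modulation evaluated at each beat's onset time (sequential by nature)
    dep <- params$ibi_mod_depth_ms / 1000
    t_on <- 0
    for (k in seq_along(ib)) {
      ib[k] <- ib[k] + dep * sin(2 * pi * params$ibi_mod_freq_hz * t_on)
      t_on <- t_on + ib[k]
    }
  }
  pmax(ib, 0.25)
}

#' Simulate a single PPG recording
#'
#' Concatenates template beats with independent truncated-normal
#' inter-beat intervals, then adds sinusoidal baseline drift and white noise.
#' Deterministic for a given `seed`.
#'
#' @param params A [morph_params()] object.
#' @param duration_s Recording length (s), default 90.
#' @param fs_hz Sampling rate (Hz), default 500.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @param subject_id Optional id stamped on the recording.
#' @return A `ppg_recording` tibble with `round(duration_s * fs_hz)` rows and
#'   a `truth` attribute: a tibble of the generated beats' onset and systolic
#'   peak sample indices (ground truth for segmentation tests).
#' @export
simulate_recording <- function(params, duration_s = 90, fs_hz = 500,
                               seed = NULL, subject_id = NULL) {
  stopifnot(inherits(params, "morph_params"))
  gen <- function() {
    n <- round(duration_s * fs_hz)
    ibis <- draw_ibis(params, duration_s)
    onsets <- cumsum(c(0, ibis))
    onsets <- onsets[onsets < duration_s]
    on_idx <- round(onsets * fs_hz) + 1L
    x <- numeric(n)
    peak_idx <- integer(length(on_idx))
    for (k in seq_along(on_idx)) {
      i0 <- on_idx[k]
      i1 <- if (k < length(on_idx)) on_idx[k + 1L] - 1L else n
      if (i1 < i0) { peak_idx[k] <- NA_integer_; next }
      len <- i1 - i0 + 1L
      beat_d <- len / fs_hz
      y <- simulate_beat_template(params, beat_d, fs_hz)
      rel_pk <- attr(y, "peak_idx", exact = TRUE)
      y <- y[seq_len(len)]
      x[i0:i1] <- y
      pk <- i0 + rel_pk - 1L
      peak_idx[k] <- if (rel_pk <= len && pk <= n) pk else NA_integer_
    }
    t <- (seq_len(n) - 1) / fs_hz
    if (params$drift_amp > 0) {
      x <- x + params$drift_amp * sin(2 * pi * params$drift_freq_hz * t)
    }
    if (params$noise_sd > 0) x <- x + rnorm(n, 0, params$noise_sd)
    truth <- tibble(beat = seq_along(on_idx), onset_idx = on_idx,
                    peak_idx = peak_idx)
    truth <- truth[!is.na(truth$peak_idx), ]
    rec <- as_ppg_recording(tibble(t_s = t, ppg = x), fs_hz = fs_hz,
                            subject_id = subject_id)
    attr(rec, "truth") <- truth
    attr(rec, "params") <- params
    rec
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

# --- cohort -----------------------------------------------------------------

draw_subject_params <- function(profile) {
  pm <- profile$params_mean
  cv <- profile$params_cv
  vals <- unclass(pm)
  for (f in names(cv)) {
    if (cv[[f]] > 0) vals[[f]] <- rlnorm_cv(1, vals[[f]], cv[[f]])
  }
  # re-validate through the constructor; clamp the few fields whose draws
  # could leave the legal range
  vals$heart_rate_bpm <- min(max(vals$heart_rate_bpm, 30), 200)
  vals$refl_amp_frac <- min(vals$refl_amp_frac, 0.95)
  vals$notch_depth_frac <- min(vals$notch_depth_frac, 1)
  vals$refl_delay_s <- min(vals$refl_delay_s, 0.95 * 60 / vals$heart_rate_bpm)
  do.call(morph_params, vals)
}

draw_sbp <- function(profile) {
  for (i in 1:10000) {
    s <- round(rnorm(1, profile$sbp_mean, profile$sbp_sd))
    ok <- s > 50 && s < 300 && assign_sbp_group(s) == profile$group_id
    if (ok) return(s)
  }
  abort(sprintf("Could not draw an SBP inside group %d's interval.", profile$group_id))
}

#' Simulate a full four-group PPG cohort
#'
#' Draws per-subject SBP values (resampled into each group's interval) and
#' per-subject morphology parameters (log-normal around the group means),
#' then simulates one recording per subject. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `recordings` (named list of `ppg_recording`
#'   tibbles), `meta` (tibble: `subject_id`, `sbp_mmHg`, `group_id`, `seed`)
#'   and `params` (tibble of the drawn per-subject morphology parameters —
#'   the simulation ground truth).
#' @examples
#' coh <- simulate_cohort(cohort_spec(2, duration_s = 10, seed = 42))
#' coh$meta
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    rows <- list(); recs <- list(); par_rows <- list()
    i <- 0L
    for (profile in spec$profiles) {
      for (j in seq_len(spec$n_per_group)) {
        i <- i + 1L
        sid <- sprintf("S%03d", i)
        sbp <- draw_sbp(profile)
        pars <- draw_subject_params(profile)
        sseed <- sample.int(.Machine$integer.max - 1L, 1L)
        recs[[sid]] <- simulate_recording(pars, spec$duration_s, spec$fs_hz,
                                          seed = sseed, subject_id = sid)
        rows[[i]] <- tibble(subject_id = sid, sbp_mmHg = sbp,
                            group_id = profile$group_id, seed = sseed)
        par_rows[[i]] <- tibble(subject_id = sid, !!!unclass(pars))
      }
    }
    list(recordings = recs, meta = bind_rows(rows), params = bind_rows(par_rows))
  })
}

#' Write a simulated cohort to disk
#'
#' One `<subject_id>.csv` per recording (header `t_s,ppg`) plus `cohort.csv`
#' with columns `subject_id,sbp_mmHg,group_id,seed`.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(cohort$recordings)) {
    write_recording(cohort$recordings[[sid]], file.path(dir, paste0(sid, ".csv")))
  }
  readr::write_csv(cohort$meta, file.path(dir, "cohort.csv"))
  invisible(dir)
}
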
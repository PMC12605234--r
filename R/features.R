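# canonical feature column order of the per-subject table
feature_columns <- function() {
  c("pulse_rate", "Ts", "Td", "Ts_Td", "Ss", "Ds", "Area", "P1", "P2",
    "deltaT", "SDNN", "RMSSD", "PNN50",
    "s1_10", "s1_8", "s1_6", "s1_5", "s1_3", "s1_2",
    "H1", "H2", "H3", "H4", "H2_H1", "H3_H1", "H4_H1",
    "LF", "HF", "LF_HF")
}

# the 25 features entering the group comparison (raw harmonic magnitudes are
# subject-scale dependent; their ratios carry the information)
comparison_features <- function() {
  setdiff(feature_columns(), c("H1", "H2", "H3", "H4"))
}

feature_category <- function(feature) {
  dplyr::case_when(
    grepl("^s1_", feature) ~ "Waveform sharpness",
    feature %in% c("Ts", "Td", "Ts_Td", "deltaT") ~ "Time interval",
    feature %in% c("Ss", "Ds") ~ "Slope",
    feature %in% c("SDNN", "RMSSD", "PNN50", "pulse_rate") ~ "HRV",
    feature %in% c("P1", "P2") ~ "Peak",
    feature == "Area" ~ "Area",
    TRUE ~ "Frequency-domain"
  )
}

#' Aggregate per-beat morphology into one feature row
#'
#' Arithmetic mean over retained beats for each per-beat feature (`P2` and
#' `deltaT` averaged over beats where the reflected peak exists), pulse rate
#' as 60 over the mean NN interval.
#'
#' @param morph Per-beat tibble from [beat_morphology()].
#' @param sharp Per-beat tibble from [sharpness_widths()].
#' @param nn NN tibble from [nn_intervals()].
#' @return One-row tibble with the time-domain feature columns plus
#'   contributing-beat counts `n_beats`, `n_beats_p2`.
#' @export
aggregate_beats <- function(morph, sharp, nn) {
  if (nrow(morph) < 3L) abort("Need at least 3 retained beats to aggregate.")
  m <- function(v) mean(v, na.rm = TRUE)
  sw <- tapply(sharp$width, sharp$n, m)
  wide <- as_tibble(as.list(setNames(as.numeric(sw),
                                     paste0("s1_", names(sw)))))
  out <- tibble(
    pulse_rate = 60 / mean(nn$nn_s),
    Ts = m(morph$Ts), Td = m(morph$Td), Ts_Td = m(morph$Ts_Td),
    Ss = m(morph$Ss), Ds = m(morph$Ds), Area = m(morph$Area),
    P1 = m(morph$P1), P2 = m(morph$P2), deltaT = m(morph$deltaT),
    n_beats = nrow(morph), n_beats_p2 = sum(!morph$p2_missing)
  )
  dplyr::bind_cols(out, wide)
}

#' Full feature vector of one recording
#'
#' Runs the complete extraction chain on a raw recording: band-pass filter,
#' quality mask, beat segmentation with fiducials, per-beat morphology and
#' sharpness averaged over the usable beats, time-domain and spectral
#' pulse-rate variability, and FFT harmonic amplitudes with their ratios.
#' Amplitude-bearing features are computed on the filtered, unnormalized
#' signal, so they keep the sensor's units.
#'
#' @param rec A raw recording data frame.
#' @param config A [ppg_config()] (or named-list overrides).
#' @param subject_id Optional id for the output row.
#' @return A one-row tibble with columns `subject_id`, the 29 feature
#'   columns (see [feature_columns()]) and beat counts. Spectral PRV fields
#'   are `NA` when the recording is too short for them.
#' @export
recording_features <- function(rec, config = ppg_config(), subject_id = NULL) {
  cfg <- as_ppg_config(config)
  subject_id <- subject_id %||% rec_subject(rec)
  rec <- as_ppg_recording(rec, subject_id = subject_id)

  filt <- bandpass_filter(rec, hp_hz = cfg$filter$hp_hz,
                          lp_hz = cfg$filter$lp_hz, order = cfg$filter$order)
  filt <- quality_mask(filt, window_s = cfg$qc$window_s,
                       z_thresh = cfg$qc$z_thresh)
  if (!any(filt$usable)) abort("Recording fully masked by quality control.")

  beats <- segment_beats(filt, smooth_s = cfg$segment$smooth_s,
                         refractory_s = cfg$segment$refractory_s,
                         prominence_frac = cfg$segment$prominence_frac)
  nn <- nn_intervals(beats)

  win <- cfg$aggregate$window_s
  if (!is.null(win)) {
    keep <- beats$end_s <= win
    if (sum(keep) >= 3L) {
      beats <- beats[keep, ]
      nn <- nn[nn$time_s <= win, ]
    }
  }

  morph <- beat_morphology(filt, beats)
  sharp <- sharpness_widths(filt, beats)
  td <- aggregate_beats(morph, sharp, nn)

  hrv <- hrv_time(nn$nn_s * 1000)
  prv <- tryCatch(
    prv_spectrum(nn, resample_hz = cfg$prv$resample_hz, lf = cfg$prv$lf,
                 hf = cfg$prv$hf, nperseg = cfg$prv$welch_nperseg,
                 overlap = cfg$prv$welch_overlap),
    error = function(e) tibble(LF = NA_real_, HF = NA_real_, LF_HF = NA_real_)
  )
  harm <- harmonic_spectrum(filt, pulse_rate_bpm = td$pulse_rate,
                            pad_factor = cfg$harmonics$pad_factor,
                            power = cfg$harmonics$power)

  out <- dplyr::bind_cols(
    tibble(subject_id = subject_id %||% NA_character_),
    td,
    tibble(SDNN = hrv$SDNN, RMSSD = hrv$RMSSD, PNN50 = hrv$PNN50),
    dplyr::select(harm, -"f0_hz"),
    prv
  )
  dplyr::select(out, "subject_id", all_of(feature_columns()),
                "n_beats", "n_beats_p2")
}
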
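#' Harmonic amplitudes of the pulse waveform
#'
#' Removes the mean from the longest contiguous usable stretch of the
#' recording, zero-pads it (default to four times its length), applies the
#' FFT, and reads off the fundamental and the first four harmonic
#' magnitudes. The fundamental is the largest spectral magnitude within
#' 20% of the supplied pulse rate; each harmonic `k` is the largest
#' magnitude within `0.2 * f0` of `k * f0`, which tolerates the spectral
#' broadening that beat-to-beat interval variability produces. Magnitudes
#' are normalized by the unpadded segment length so a unit sinusoid yields
#' 0.5 regardless of padding.
#'
#' @param rec A filtered recording data frame (`usable` honoured).
#' @param pulse_rate_bpm Pulse rate from segmentation, beats/min.
#' @param pad_factor Zero-padding factor (>= 1; default 4).
#' @param power If `TRUE`, report squared magnitudes (harmonic power) instead
#'   of amplitudes; the ratios change accordingly.
#' @return One-row tibble: `f0_hz`, `H1`..`H4`, `H2_H1`, `H3_H1`, `H4_H1`.
#' @examples
#' t <- seq(0, 20, by = 1 / 100)
#' rec <- as_ppg_recording(tibble::tibble(t_s = t, ppg = sin(2 * pi * 1.2 * t)))
#' harmonic_spectrum(rec, pulse_rate_bpm = 72)
#' @export
harmonic_spectrum <- function(rec, pulse_rate_bpm, pad_factor = 4,
                              power = FALSE) {
  fs <- rec_fs(rec)
  check_number(pulse_rate_bpm, "pulse_rate_bpm", 20, 220)
  use <- rec_usable(rec)
  # longest contiguous usable run
  r <- rle(use)
  ends <- cumsum(r$lengths); begins <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) abort("No usable samples for harmonic analysis.")
  best <- runs[which.max(r$lengths[runs])]
  x <- rec$ppg[begins[best]:ends[best]]
  n <- length(x)
  if (n < 4 * fs) abort("Usable segment too short for harmonic analysis (< 4 s).")
  x <- x - mean(x)
  m <- max(n, ceiling(pad_factor * n))
  # |FFT| / n: a unit-amplitude sinusoid filling the segment reads 0.5,
  # independent of the padding factor
  mag <- Mod(fft(c(x, numeric(m - n))))[seq_len(floor(m / 2))] / n
  freq <- (seq_len(floor(m / 2)) - 1) * fs / m

  f_exp <- pulse_rate_bpm / 60
  win <- which(freq >= 0.8 * f_exp & freq <= 1.2 * f_exp)
  if (!length(win) || max(mag[win]) <= 1e-12) abort("fundamental not found")
  f0 <- freq[win[which.max(mag[win])]]

  H <- vapply(1:4, function(k) {
    wk <- which(freq >= k * f0 - 0.2 * f0 & freq <= k * f0 + 0.2 * f0)
    if (!length(wk)) return(0) else max(mag[wk])
  }, numeric(1))
  if (power) H <- H^2
  ratios <- harmonic_ratios(H)
  tibble(f0_hz = f0, H1 = H[1], H2 = H[2], H3 = H[3], H4 = H[4],
         H2_H1 = ratios[1], H3_H1 = ratios[2], H4_H1 = ratios[3])
}

#' Harmonic ratios Hk/H1
#'
#' @param H Numeric vector of at least two harmonic magnitudes, fundamental
#'   first.
#' @return Numeric vector `H[2]/H[1], H[3]/H[1], ...`.
#' @export
harmonic_ratios <- function(H) {
  if (length(H) < 2L) abort("Need at least H1 and H2.")
  if (H[1] <= 0) abort("H1 is zero: cannot normalize harmonic magnitudes.")
  H[-1] / H[1]
}
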
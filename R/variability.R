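# implausible-interval gate applied before any variability statistic
clean_nn_ms <- function(nn_ms) {
  ok <- nn_ms > 250 & nn_ms < 2000
  if (any(!ok)) {
    inform(sprintf("NN cleaning: %d interval(s) outside (250, 2000) ms removed.",
                   sum(!ok)))
  }
  nn_ms[ok]
}

#' Time-domain pulse-rate variability
#'
#' `SDNN` is the sample standard deviation (n-1 denominator) of the NN
#' intervals, `RMSSD` the root mean square of successive differences, and
#' `PNN50` the percentage of successive differences strictly exceeding
#' 50 ms. Intervals outside the plausible (250, 2000) ms range are removed
#' first.
#'
#' @param nn NN intervals in milliseconds (numeric vector), or the tibble
#'   returned by [nn_intervals()] (then `nn_s` is converted to ms).
#' @return A one-row tibble: `SDNN`, `RMSSD`, `PNN50` (ms, ms, percent) and
#'   `n_nn`, the interval count used.
#' @examples
#' hrv_time(c(800, 860, 800))   # RMSSD 60, PNN50 100
#' @export
hrv_time <- function(nn) {
  nn_ms <- if (is.data.frame(nn)) nn$nn_s * 1000 else as.numeric(nn)
  nn_ms <- clean_nn_ms(nn_ms)
  if (length(nn_ms) < 3L) abort("Need at least 3 plausible NN intervals.")
  d <- diff(nn_ms)
  tibble(
    SDNN = sd(nn_ms),
    RMSSD = sqrt(mean(d^2)),
    PNN50 = 100 * mean(abs(d) > 50),
    n_nn = length(nn_ms)
  )
}

# Welch power spectral density: Hann window, mean-detrended overlapping
# segments, one-sided density such that sum(psd) * df equals the signal
# variance (for a fully resolved spectrum)
welch_psd <- function(x, fs, nperseg = 256, overlap = 0.5) {
  n <- length(x)
  nper <- min(nperseg, n)
  step <- max(1L, floor(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nper) - 1) / (nper - 1))
  norm <- fs * sum(w^2)
  nfreq <- floor(nper / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / norm
    acc <- acc + p[seq_len(nfreq)]
  }
  psd <- acc / length(starts)
  # one-sided scaling: double everything except DC (and Nyquist when nper even)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nper %% 2L == 0L) dbl[nfreq] <- 1
  tibble(freq_hz = (seq_len(nfreq) - 1) * fs / nper, psd = psd * dbl)
}

band_power <- function(spec, lo, hi, right_closed = TRUE) {
  df <- spec$freq_hz[2] - spec$freq_hz[1]
  sel <- spec$freq_hz >= lo &
    (if (right_closed) spec$freq_hz <= hi else spec$freq_hz < hi)
  sum(spec$psd[sel]) * df
}

#' Spectral pulse-rate variability (LF, HF, LF/HF)
#'
#' Interpolates the NN interval series (seconds, against the time of each
#' interval's ending peak) onto a uniform grid with a cubic spline, removes
#' the mean, estimates the power spectral density with Welch's method
#' (Hann window, 50% overlap), and integrates the low-frequency
#' (0.04--0.15 Hz, right-open) and high-frequency (0.15--0.40 Hz) bands by
#' the rectangle rule.
#'
#' @param nn Tibble from [nn_intervals()] (`time_s`, `nn_s`).
#' @param resample_hz Uniform resampling rate, default 4 Hz.
#' @param lf,hf Band edges in Hz.
#' @param nperseg,overlap Welch segment length (samples) and overlap
#'   fraction. The 256-sample default spans 64 s at 4 Hz, enough to resolve
#'   the 0.04 Hz band edge.
#' @return One-row tibble: `LF`, `HF` (s^2), `LF_HF` (`NA` when HF is zero).
#' @export
prv_spectrum <- function(nn, resample_hz = 4, lf = c(0.04, 0.15),
                         hf = c(0.15, 0.40), nperseg = 256, overlap = 0.5) {
  stopifnot(is.data.frame(nn), all(c("time_s", "nn_s") %in% names(nn)))
  keep <- nn$nn_s * 1000 > 250 & nn$nn_s * 1000 < 2000
  nn <- nn[keep, ]
  if (nrow(nn) < 30L) abort("Need at least 30 plausible NN intervals for spectral analysis.")
  span <- diff(range(nn$time_s))
  if (span < 60) abort("NN series must span at least 60 s for spectral analysis.")
  grid <- seq(min(nn$time_s), max(nn$time_s), by = 1 / resample_hz)
  y <- spline(nn$time_s, nn$nn_s, xout = grid)$y
  y <- y - mean(y)
  spec <- welch_psd(y, resample_hz, nperseg = nperseg, overlap = overlap)
  LF <- band_power(spec, lf[1], lf[2], right_closed = FALSE)
  HF <- band_power(spec, hf[1], hf[2], right_closed = TRUE)
  tibble(LF = LF, HF = HF, LF_HF = if (HF > 0) LF / HF else NA_real_)
}
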
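#' Zero-phase band-pass filter a PPG recording
#'
#' Applies a 4th-order Butterworth high-pass (default 0.5 Hz) and a 4th-order
#' Butterworth low-pass (default 8 Hz), each forward-backward
#' (zero-phase), so fiducial timing is not distorted. Sample count and
#' sampling rate are preserved; DC is removed.
#'
#' @param rec A recording data frame (`t_s`, `ppg`).
#' @param hp_hz,lp_hz High-/low-pass cutoff frequencies in Hz.
#' @param order Butterworth order for each stage.
#' @return The filtered recording (tibble, same shape).
#' @export
bandpass_filter <- function(rec, hp_hz = 0.5, lp_hz = 8, order = 4) {
  fs <- rec_fs(rec)
  if (fs < 2.5 * lp_hz) {
    abort(sprintf("Sampling rate %g Hz is too low for a %g Hz low-pass edge.", fs, lp_hz))
  }
  # settling ~ 1/hp_hz (2 s at the default); require 3x that
  min_s <- 3 / hp_hz
  if (nrow(rec) < min_s * fs) {
    abort(sprintf(
      "Recording too short to filter reliably: need at least %.0f s at a %g Hz high-pass.",
      min_s, hp_hz))
  }
  hp <- butter(order, hp_hz / (fs / 2), type = "high")
  lp <- butter(order, lp_hz / (fs / 2), type = "low")
  # remove the mean and pad by reflection before the forward-backward
  # passes: filtfilt alone starts from zero state, which leaves large edge
  # transients (and a DC input would not come out as zero). Even (mirror)
  # reflection keeps the padding inside the signal's amplitude range, so the
  # warm-up swing stays comparable to the signal itself.
  x <- rec$ppg - mean(rec$ppg)
  n <- length(x)
  p <- min(n - 1L, round(3 / hp_hz * fs))
  xp <- c(x[(p + 1L):2], x, x[(n - 1L):(n - p)])
  y <- filtfilt(lp, filtfilt(hp, xp))[(p + 1L):(p + n)]
  out <- as_tibble(rec)
  out$ppg <- y
  rec_restamp(out, rec)
}

#' Min-max normalize a recording to the unit interval
#'
#' Rescales the signal to `[0, 1]` using the minimum and maximum over the
#' usable (unmasked) region. Order-preserving and idempotent. Amplitude-bearing
#' features are computed on the unnormalized filtered signal; this scaling
#' serves plotting and any scale-free quantity.
#'
#' @param rec A recording data frame.
#' @return The rescaled recording.
#' @export
normalize_amplitude <- function(rec) {
  use <- rec_usable(rec)
  x <- rec$ppg[use]
  if (!length(x)) abort("No usable samples to normalize over.")
  lo <- min(x); hi <- max(x)
  if (hi == lo) abort("Degenerate signal: amplitude range is zero.")
  out <- as_tibble(rec)
  out$ppg <- (rec$ppg - lo) / (hi - lo)
  rec_restamp(out, rec)
}

#' Automated signal-quality mask
#'
#' Flags windows whose amplitude range is an outlier of the per-window range
#' distribution (robust z-score above `z_thresh`) or that contain clipping
#' (five or more consecutive identical samples at the global extremes). A
#' surrogate for manual artifact inspection; downstream stages drop beats
#' that touch masked samples.
#'
#' @param rec A (typically filtered) recording data frame.
#' @param window_s Window length in seconds (default 2).
#' @param z_thresh Robust z-score threshold on the window range (default 3.5).
#' @return The recording with a logical `usable` column; the masked fraction
#'   is reported via a message.
#' @export
quality_mask <- function(rec, window_s = 2, z_thresh = 3.5) {
  fs <- rec_fs(rec)
  n <- nrow(rec)
  x <- rec$ppg
  usable <- rep(TRUE, n)

  w <- max(2L, round(window_s * fs))
  starts <- seq(1L, n, by = w)
  rng <- vapply(starts, function(s) {
    seg <- x[s:min(s + w - 1L, n)]
    diff(range(seg))
  }, numeric(1))
  med <- median(rng)
  # MAD floor at 10% of the median range: homogeneous clean recordings
  # (near-identical window ranges, filter warm-up) must not produce huge
  # z-scores out of ordinary variation; real artifacts are orders larger
  scale <- max(mad(rng), 0.1 * med, .Machine$double.eps)
  z <- (rng - med) / scale
  for (k in which(z > z_thresh)) {
    usable[starts[k]:min(starts[k] + w - 1L, n)] <- FALSE
  }

  # clipping: runs of >= 5 identical samples sitting at the global extremes
  r <- rle(x)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  extreme <- r$lengths >= 5L & (r$values == max(x) | r$values == min(x))
  for (k in which(extreme)) usable[begins[k]:ends[k]] <- FALSE

  frac <- mean(!usable)
  if (frac > 0) inform(sprintf("quality_mask: %.1f%% of samples masked out.", 100 * frac))
  out <- as_tibble(rec)
  out$usable <- usable
  rec_restamp(out, rec)
}
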
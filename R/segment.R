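# --- systolic peak detection ------------------------------------------------

# pulse frequency from the signal autocorrelation: the highest-correlation
# lag between 0.3 s (200 bpm) and 2 s (30 bpm). Robust against waveforms
# whose second harmonic outweighs the fundamental (reflected wave near half
# the beat period), where a spectral-peak estimate would double the rate.
estimate_f0 <- function(x, fs) {
  # decimate to ~50 Hz first: lag resolution of 20 ms is ample for a
  # refractory estimate and keeps the FFT small
  dec <- max(1L, floor(fs / 50))
  x <- x[seq(1L, length(x), by = dec)]
  fs <- fs / dec
  x <- x - mean(x)
  n <- length(x)
  lo <- round(0.3 * fs); hi <- min(round(2 * fs), n - 1L)
  if (hi <= lo || all(x == 0)) return(NA_real_)
  # FFT-based autocorrelation (zero-padded to avoid circular wrap)
  m <- 2^ceiling(log2(2 * n))
  sp <- fft(c(x, numeric(m - n)))
  ac <- Re(fft(sp * Conj(sp), inverse = TRUE))[seq_len(hi + 1L)]
  lag <- which.max(ac[(lo + 1L):(hi + 1L)]) + lo - 1L
  if (ac[lag + 1L] <= 0) return(NA_real_)
  fs / lag
}

# topographic prominence of each peak: height above the higher of the two
# flanking minima (minima taken towards the neighbouring peaks / edges)
peak_prominence <- function(x, peaks) {
  bounds <- c(1L, peaks, length(x))
  vapply(seq_along(peaks), function(k) {
    p <- peaks[k]
    left <- min(x[bounds[k]:p])
    right <- min(x[p:bounds[k + 2L]])
    x[p] - max(left, right)
  }, numeric(1))
}

#' Detect systolic peaks
#'
#' Smooths the signal with a short moving average, takes positive-to-negative
#' zero crossings of the first derivative as candidate maxima, refines each
#' to the local maximum of the raw signal, then rejects low-prominence
#' candidates (below 20% of the median prominence) and enforces a
#' heart-rate-adaptive refractory period (70% of the estimated pulse period,
#' floored at 0.3 s) that keeps the taller of any conflicting pair — this is
#' what rejects reflected-wave (P2) maxima. Peaks in masked-out regions are
#' dropped.
#'
#' @param rec A recording data frame (filtered; `usable` column honoured).
#' @param smooth_s Moving-average width in seconds before differentiation.
#' @param refractory_s Minimum peak spacing; `NULL` (default) = adaptive.
#' @param prominence_frac Prominence floor as a fraction of the median
#'   candidate prominence.
#' @return Integer vector of strictly increasing peak sample indices.
#' @export
detect_systolic_peaks <- function(rec, smooth_s = 0.025, refractory_s = NULL,
                                  prominence_frac = 0.2) {
  fs <- rec_fs(rec)
  x <- rec$ppg
  n <- length(x)
  if (n < 2 * fs) abort("Need at least 2 s of signal to detect beats.")
  k <- max(3L, round(smooth_s * fs))
  s <- moving_average(x, k)
  d <- diff(s)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L

  # refine each candidate to the raw-signal maximum nearby
  half <- max(1L, (k - 1L) %/% 2L)
  cand <- vapply(cand, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  cand <- sort(unique(cand))
  if (length(cand) >= 2L) {
    prom <- peak_prominence(x, cand)
    cand <- cand[prom >= prominence_frac * median(prom)]
  }

  if (is.null(refractory_s)) {
    f0 <- estimate_f0(x, fs)
    refractory_s <- if (is.na(f0)) 0.3 else max(0.3, 0.7 / f0)
  }
  min_gap <- round(refractory_s * fs)
  # greedy: visit candidates from tallest to shortest, keep those not inside
  # an accepted peak's refractory window
  keep <- logical(length(cand))
  for (k2 in order(x[cand], decreasing = TRUE)) {
    p <- cand[k2]
    if (!any(keep & abs(cand - p) < min_gap)) keep[k2] <- TRUE
  }
  peaks <- sort(cand[keep])

  use <- rec_usable(rec)
  peaks <- peaks[use[peaks]]
  if (length(peaks) < 3L) abort("no beats detected")
  peaks
}

#' Detect inter-beat valleys
#'
#' One valley per consecutive peak pair: the signal minimum on the open
#' interval between them, earliest index on ties.
#'
#' @param rec A recording data frame.
#' @param peaks Strictly increasing peak indices (>= 2 of them).
#' @return Integer vector of `length(peaks) - 1` valley indices.
#' @export
detect_valleys <- function(rec, peaks) {
  if (length(peaks) < 2L) abort("Need at least 2 peaks to place valleys.")
  x <- rec$ppg
  vapply(seq_len(length(peaks) - 1L), function(k) {
    lo <- peaks[k] + 1L
    hi <- peaks[k + 1L] - 1L
    if (hi < lo) abort("Adjacent peaks with no samples between them.")
    lo + which.min(x[lo:hi]) - 1L
  }, integer(1))
}

# --- dicrotic notch / reflected peak ----------------------------------------

local_extrema <- function(s) {
  n <- length(s)
  if (n < 3L) return(list(minima = integer(), maxima = integer()))
  core <- 2:(n - 1L)
  minima <- core[s[core] < s[core - 1L] & s[core] <= s[core + 1L]]
  maxima <- core[s[core] > s[core - 1L] & s[core] >= s[core + 1L]]
  list(minima = minima, maxima = maxima)
}

#' Locate the dicrotic notch and reflected (P2) peak within one beat
#'
#' Searches the window from just after the systolic peak to 60% of the beat
#' duration for the first local minimum (notch) followed by the first local
#' maximum (P2) of the lightly smoothed signal. If the waveform is too stiff
#' or merged for interior extrema, both fiducials fall back to the first
#' local maximum of the second derivative after the peak (the inflection of
#' the runoff), flagged `fallback`. If even that fails the beat is flagged
#' `p2_missing`.
#'
#' @param rec A recording data frame.
#' @param onset_idx,peak_idx,end_idx Beat fiducial sample indices.
#' @param smooth_s Smoothing width for extremum finding.
#' @param smoothed Optional pre-smoothed copy of the whole signal (internal
#'   reuse by [segment_beats()]).
#' @return A list: `notch_idx`, `p2_idx` (NA when missing), `fallback`,
#'   `p2_missing`.
#' @export
locate_dicrotic_p2 <- function(rec, onset_idx, peak_idx, end_idx,
                               smooth_s = 0.025, smoothed = NULL) {
  fs <- rec_fs(rec)
  dur <- end_idx - onset_idx
  lo <- peak_idx + 1L
  hi <- min(end_idx, peak_idx + floor(0.6 * dur))
  if (hi - lo < 3L) {
    return(list(notch_idx = NA_integer_, p2_idx = NA_integer_,
                fallback = FALSE, p2_missing = TRUE))
  }
  if (is.null(smoothed)) {
    smoothed <- moving_average(rec$ppg, max(3L, round(smooth_s * fs)))
  }
  seg <- smoothed[lo:hi]
  ext <- local_extrema(seg)
  if (length(ext$minima)) {
    notch <- ext$minima[1]
    after <- ext$maxima[ext$maxima > notch]
    if (length(after)) {
      return(list(notch_idx = lo + notch - 1L, p2_idx = lo + after[1] - 1L,
                  fallback = FALSE, p2_missing = FALSE))
    }
  }
  # fallback: inflection of the runoff = first local max of the 2nd derivative
  d2 <- diff(diff(seg))
  if (length(d2) >= 3L) {
    ext2 <- local_extrema(d2)
    if (length(ext2$maxima)) {
      idx <- lo + ext2$maxima[1]            # +1 for each diff, -1 for offset
      return(list(notch_idx = idx, p2_idx = idx,
                  fallback = TRUE, p2_missing = FALSE))
    }
  }
  list(notch_idx = NA_integer_, p2_idx = NA_integer_,
       fallback = FALSE, p2_missing = TRUE)
}

# --- beat assembly ----------------------------------------------------------

#' Segment a recording into valley-to-valley beats
#'
#' Runs peak and valley detection, assembles onset-peak-end triplets, locates
#' the dicrotic notch and reflected peak in each, and discards beats whose
#' duration falls outside `[0.3, 2]` s or that touch masked-out samples.
#'
#' @param rec A filtered recording data frame.
#' @param ... Passed on to [detect_systolic_peaks()].
#' @return A `ppg_beats` tibble: one row per retained beat with columns
#'   `beat`, `onset_idx`, `peak_idx`, `notch_idx`, `p2_idx`, `end_idx`, the
#'   same fiducials in seconds, and flags `fallback`, `p2_missing`. The
#'   number of discarded beats is attached as attribute `n_discarded`, the
#'   retained-peak NN intervals via [nn_intervals()].
#' @export
segment_beats <- function(rec, ...) {
  fs <- rec_fs(rec)
  peaks <- detect_systolic_peaks(rec, ...)
  valleys <- detect_valleys(rec, peaks)
  use <- rec_usable(rec)

  n_beats <- length(peaks) - 2L
  # smooth once; per-beat extremum finding reuses this vector
  k <- max(3L, round(0.025 * fs))
  smoothed <- moving_average(rec$ppg, k)

  keep <- logical(n_beats)
  notch <- p2 <- rep(NA_integer_, n_beats)
  fallback <- p2_missing <- logical(n_beats)
  onset_v <- valleys[seq_len(n_beats)]
  peak_v <- peaks[seq_len(n_beats) + 1L]
  end_v <- valleys[seq_len(n_beats) + 1L]
  for (j in seq_len(n_beats)) {
    dur <- (end_v[j] - onset_v[j]) / fs
    if (dur < 0.3 || dur > 2 || any(!use[onset_v[j]:end_v[j]])) next
    keep[j] <- TRUE
    dic <- locate_dicrotic_p2(rec, onset_v[j], peak_v[j], end_v[j],
                              smoothed = smoothed)
    notch[j] <- dic$notch_idx; p2[j] <- dic$p2_idx
    fallback[j] <- dic$fallback; p2_missing[j] <- dic$p2_missing
  }
  discarded <- sum(!keep)
  beats <- tibble(
    beat = which(keep), onset_idx = onset_v[keep], peak_idx = peak_v[keep],
    notch_idx = notch[keep], p2_idx = p2[keep], end_idx = end_v[keep],
    fallback = fallback[keep], p2_missing = p2_missing[keep]
  )
  if (nrow(beats) < 3L) abort("Fewer than 3 usable beats after segmentation.")
  beats <- mutate(beats,
    onset_s = (.data$onset_idx - 1) / fs, peak_s = (.data$peak_idx - 1) / fs,
    notch_s = (.data$notch_idx - 1) / fs, p2_s = (.data$p2_idx - 1) / fs,
    end_s = (.data$end_idx - 1) / fs
  )
  if (discarded > 0) inform(sprintf("segment_beats: %d beat(s) discarded.", discarded))
  attr(beats, "fs_hz") <- fs
  attr(beats, "n_discarded") <- discarded
  attr(beats, "subject_id") <- rec_subject(rec)
  attr(beats, "all_peak_s") <- (peaks - 1) / fs
  class(beats) <- unique(c("ppg_beats", class(beats)))
  beats
}

#' NN (peak-to-peak) interval series
#'
#' Successive time differences of consecutive retained systolic peaks — the
#' PPG analogue of the RR interval series.
#'
#' @param x A `ppg_beats` tibble from [segment_beats()] (all detected peaks
#'   are used, including the edge peaks that lack a flanking valley), or a
#'   bare numeric vector of peak times in seconds.
#' @return Tibble with `time_s` (time of the interval's ending peak) and
#'   `nn_s` (interval length, seconds).
#' @export
nn_intervals <- function(x) {
  pt <- if (is.numeric(x)) x else attr(x, "all_peak_s") %||% x$peak_s
  if (length(pt) < 2L) abort("Need at least 2 peaks for NN intervals.")
  tibble(time_s = pt[-1], nn_s = diff(pt))
}
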
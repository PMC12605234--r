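#' Per-beat time-domain morphology
#'
#' For every retained beat: the per-beat baseline is the signal value at the
#' onset valley; `P1`/`P2` are the systolic and reflected peak amplitudes
#' above it, `deltaT` the systolic-to-reflected peak delay, `Ts`/`Td` the
#' systolic (onset to peak) and diastolic (peak to end) durations, `Ss`/`Ds`
#' the chord slopes of the two limbs, and `Area` the trapezoidal integral of
#' the baseline-corrected waveform over the beat.
#'
#' @param rec The recording the beats were segmented from (filtered,
#'   unnormalized: amplitude features are in signal units).
#' @param beats A `ppg_beats` tibble.
#' @return Tibble, one row per beat: `beat`, `P1`, `P2`, `deltaT`, `Ts`,
#'   `Td`, `Ts_Td`, `Ss`, `Ds`, `Area`, `duration_s`, `p2_missing`.
#'   `P2`/`deltaT` are `NA` where the reflected peak is missing.
#' @export
beat_morphology <- function(rec, beats) {
  fs <- rec_fs(rec)
  x <- rec$ppg
  b <- x[beats$onset_idx]
  p1 <- x[beats$peak_idx] - b
  ts <- (beats$peak_idx - beats$onset_idx) / fs
  td <- (beats$end_idx - beats$peak_idx) / fs
  keep <- ts > 0 & td > 0
  if (!all(keep)) {
    inform(sprintf("beat_morphology: %d degenerate beat(s) skipped.", sum(!keep)))
  }
  p2 <- ifelse(beats$p2_missing, NA_real_, x[beats$p2_idx] - b)
  dT <- ifelse(beats$p2_missing, NA_real_, (beats$p2_idx - beats$peak_idx) / fs)
  area <- vapply(seq_len(nrow(beats)), function(j) {
    seg <- x[beats$onset_idx[j]:beats$end_idx[j]] - b[j]
    trapz_uniform(seg, 1 / fs)
  }, numeric(1))
  out <- tibble(
    beat = beats$beat, P1 = p1, P2 = p2, deltaT = dT,
    Ts = ts, Td = td, Ts_Td = ts / td,
    Ss = p1 / ts, Ds = (x[beats$end_idx] - x[beats$peak_idx]) / td,
    Area = area, duration_s = ts + td, p2_missing = beats$p2_missing
  )
  out[keep, ]
}

# interpolated crossing time (in samples, 0-based fractional) of level L:
# last upward crossing at or before `peak` / first downward crossing after it
cross_left <- function(x, L, from, peak) {
  idx <- from:(peak - 1L)
  up <- idx[x[idx] <= L & x[idx + 1L] > L]
  if (!length(up)) return(NA_real_)
  i <- up[length(up)]
  i + (L - x[i]) / (x[i + 1L] - x[i])
}

cross_right <- function(x, L, peak, to) {
  if (peak >= to) return(NA_real_)
  idx <- peak:(to - 1L)
  down <- idx[x[idx] >= L & x[idx + 1L] < L]
  if (!length(down)) return(NA_real_)
  i <- down[1]
  i + (x[i] - L) / (x[i] - x[i + 1L])
}

#' Waveform sharpness indices (normalized widths)
#'
#' For each divisor `n`, the target level sits at `P1 * (1 - 1/n)` above the
#' per-beat baseline — i.e. a fraction `(n-1)/n` of the systolic peak height.
#' The width is the time between the last upward crossing of that level
#' before the peak and the first downward crossing after it (both located by
#' sub-sample linear interpolation), normalized by the valley-to-valley beat
#' duration. Larger `n` probes closer to the apex, so widths are
#' non-increasing in `n`. Scale- and offset-invariant by construction.
#'
#' @param rec The recording data frame.
#' @param beats A `ppg_beats` tibble.
#' @param n Integer divisors; default the conventional set `10, 8, 6, 5, 3, 2`.
#' @return Tibble, one row per beat x divisor: `beat`, `n`, `width` (the
#'   normalized width, `NA` when the level is never crossed on one side).
#' @export
sharpness_widths <- function(rec, beats, n = c(10L, 8L, 6L, 5L, 3L, 2L)) {
  fs <- rec_fs(rec)
  x <- rec$ppg
  nb <- nrow(beats)
  wmat <- matrix(NA_real_, nrow = nb, ncol = length(n))
  for (j in seq_len(nb)) {
    onset <- beats$onset_idx[j]; pk <- beats$peak_idx[j]; endv <- beats$end_idx[j]
    b <- x[onset]
    p1 <- x[pk] - b
    if (p1 <= 0) next
    dur <- (endv - onset) / fs
    for (i in seq_along(n)) {
      L <- b + p1 * (1 - 1 / n[i])
      tl <- cross_left(x, L, onset, pk)
      tr <- cross_right(x, L, pk, endv)
      if (!is.na(tl) && !is.na(tr)) wmat[j, i] <- ((tr - tl) / fs) / dur
    }
  }
  tibble(
    beat = rep(beats$beat, each = length(n)),
    n = rep(as.integer(n), nb),
    width = as.numeric(t(wmat))
  )
}
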
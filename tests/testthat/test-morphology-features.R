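test_that("triangular beat geometry is recovered exactly", {
  fs <- 500
  t <- seq(0, 0.5, by = 1 / fs)
  y <- pmax(0, pmin(t / 0.1, (0.5 - t) / 0.4))
  rec <- as_ppg_recording(tibble::tibble(t_s = t, ppg = y))
  beats <- tibble::tibble(beat = 1L, onset_idx = 1L, peak_idx = 51L,
                          notch_idx = NA_integer_, p2_idx = NA_integer_,
                          end_idx = length(y), fallback = FALSE,
                          p2_missing = TRUE)
  m <- beat_morphology(rec, beats)
  expect_equal(m$Ts, 0.1)
  expect_equal(m$Td, 0.4)
  expect_equal(m$Ts_Td, 0.25)
  expect_equal(m$Ss, 10)
  expect_equal(m$Ds, -2.5)
  expect_equal(m$P1, 1)
  expect_equal(m$Area, 0.25, tolerance = 1e-6)
  expect_true(is.na(m$P2) && is.na(m$deltaT))
})

test_that("sharpness of a symmetric triangle follows 2a(1-h)", {
  ab <- analytic_beat("triangle", rise_s = 0.1, fall_s = 0.1, beat_s = 1.0)
  w <- sharpness_widths(ab$rec, ab$beats)
  h <- (w$n - 1) / w$n
  expect_equal(w$width, 2 * 0.1 * (1 - h), tolerance = 1e-6)
  expect_equal(w$width[w$n == 2], 0.100, tolerance = 1e-6)
  expect_equal(w$width[w$n == 10], 0.020, tolerance = 1e-6)
})

test_that("sharpness of a Gaussian pulse follows 2*sigma*sqrt(2*log(1/h))", {
  ab <- analytic_beat("gauss", sigma = 0.04, center = 0.35, beat_s = 1.0)
  w <- sharpness_widths(ab$rec, ab$beats)
  h <- (w$n - 1) / w$n
  expected <- 2 * 0.04 * sqrt(2 * log(1 / h))
  expect_true(all(abs(w$width - expected) / expected < 0.01))
})

test_that("rectangular pulse has the same width at every level", {
  ab <- analytic_beat("rect", rise_s = 0.1, beat_s = 1.0)
  w <- sharpness_widths(ab$rec, ab$beats)
  expect_lt(diff(range(w$width)), 2 / fs_default)
})

test_that("sharpness is invariant to affine amplitude transforms", {
  r <- simulate_recording(morph_params(ibi_sd_ms = 20), 20, 500, seed = 55)
  beats <- quiet(segment_beats(r))
  w0 <- sharpness_widths(r, beats)
  for (case in list(c(3.7, 0), c(1, 42), c(-2.5, 10))) {
    r2 <- r
    r2$ppg <- case[1] * r$ppg + case[2]
    if (case[1] < 0) next  # inverted signals are no longer pulse waveforms
    w2 <- sharpness_widths(r2, beats)
    expect_equal(w2$width, w0$width, tolerance = 1e-9)
  }
})

test_that("widths are non-increasing in n for unimodal beats", {
  r <- simulate_recording(morph_params(ibi_sd_ms = 25), 30, 500, seed = 56)
  beats <- quiet(segment_beats(r))
  w <- sharpness_widths(r, beats)
  by_beat <- split(w, w$beat)
  for (b in by_beat) {
    b <- b[order(b$n), ]                 # n ascending: 2,3,5,6,8,10
    expect_true(all(diff(b$width[!is.na(b$width)]) <= 1e-12))
  }
})

test_that("Ss * Ts equals P1 for every beat by construction", {
  r <- simulate_recording(morph_params(noise_sd = 3, ibi_sd_ms = 25), 20, 500,
                          seed = 57)
  filt <- quiet(quality_mask(bandpass_filter(r)))
  beats <- quiet(segment_beats(filt))
  m <- beat_morphology(filt, beats)
  expect_equal(m$Ss * m$Ts, m$P1, tolerance = 1e-12)
})

test_that("aggregation means, pulse rate arithmetic and P2 counting", {
  ab <- analytic_beat("triangle", rise_s = 0.1, fall_s = 0.1, beat_s = 1.0)
  m1 <- beat_morphology(ab$rec, ab$beats)
  s1 <- sharpness_widths(ab$rec, ab$beats)
  # two identical beats -> aggregate equals the single-beat values
  m2 <- dplyr::bind_rows(m1, dplyr::mutate(m1, beat = 2L))
  m3 <- dplyr::bind_rows(m2, dplyr::mutate(m1, beat = 3L))
  s3 <- dplyr::bind_rows(s1, dplyr::mutate(s1, beat = 2L),
                         dplyr::mutate(s1, beat = 3L))
  nn <- tibble::tibble(time_s = c(1, 2), nn_s = c(1, 1))
  agg <- aggregate_beats(m3, s3, nn)
  expect_equal(agg$pulse_rate, 60)
  expect_equal(agg$Ts, m1$Ts)
  expect_equal(agg$s1_2, s1$width[s1$n == 2])
  expect_identical(agg$n_beats, 3L)
  expect_identical(agg$n_beats_p2, 0L)

  # P2 present in one of three beats -> averaged over that one, count = 1
  m3$P2 <- c(0.5, NA, NA); m3$deltaT <- c(0.3, NA, NA)
  m3$p2_missing <- c(FALSE, TRUE, TRUE)
  agg2 <- aggregate_beats(m3, s3, nn)
  expect_equal(agg2$P2, 0.5)
  expect_equal(agg2$deltaT, 0.3)
  expect_identical(agg2$n_beats_p2, 1L)

  expect_error(aggregate_beats(m1, s1, nn), "3 retained beats")
})

test_that("mean sharpness tracks the generating systolic width across subjects", {
  coh <- simulate_cohort(cohort_spec(25, duration_s = 30, seed = 77))
  fx <- quiet(extract_features(coh$recordings))
  j <- dplyr::inner_join(fx, coh$params, by = "subject_id")
  expect_gt(cor(j$s1_2, j$sys_width_s), 0.95)
})
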
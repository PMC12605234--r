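# fixtures are built in code: analytic pulse shapes with known geometry,
# plus small simulated recordings

fs_default <- 500

# recording holding a single analytic beat on [0, beat_s]; returns the
# recording and a one-row beats tibble with exact fiducials
analytic_beat <- function(shape = c("triangle", "gauss", "rect"),
                          rise_s = 0.1, fall_s = 0.1, sigma = 0.04,
                          center = 0.35, beat_s = 1.0, fs = fs_default) {
  shape <- match.arg(shape)
  t <- seq(0, beat_s, by = 1 / fs)
  y <- switch(shape,
    triangle = pmax(0, pmin(t / rise_s, (rise_s + fall_s - t) / fall_s)),
    gauss = exp(-(t - center)^2 / (2 * sigma^2)),
    rect = as.numeric(t >= rise_s & t < 2 * rise_s)
  )
  rec <- as_ppg_recording(tibble::tibble(t_s = t, ppg = y))
  pk <- which.max(y)
  beats <- tibble::tibble(
    beat = 1L, onset_idx = 1L, peak_idx = pk,
    notch_idx = NA_integer_, p2_idx = NA_integer_,
    end_idx = length(y), fallback = FALSE, p2_missing = TRUE,
    onset_s = 0, peak_s = t[pk], notch_s = NA_real_, p2_s = NA_real_,
    end_s = beat_s
  )
  attr(beats, "fs_hz") <- fs
  list(rec = rec, beats = beats)
}

# NN series tibble from interval values (ms) laid end to end
nn_series <- function(nn_ms) {
  t <- cumsum(nn_ms) / 1000
  tibble::tibble(time_s = t, nn_s = nn_ms / 1000)
}

# sinusoidally modulated NN series: base 1000 ms + depth*sin(2 pi f t)
modulated_nn <- function(freq_hz, depth_ms = 50, total_s = 120) {
  t <- 0; out <- numeric(0)
  while (t < total_s) {
    nn <- 1 + (depth_ms / 1000) * sin(2 * pi * freq_hz * t)
    t <- t + nn
    out <- c(out, nn)
  }
  tibble::tibble(time_s = cumsum(out), nn_s = out)
}

quiet <- function(expr) suppressMessages(expr)

# independent rank-based Kruskal-Wallis + epsilon-squared oracle
kw_brute <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(ns * rbar^2) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / corr
  list(H = H, eps2 = H / (N - 1))
}
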
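# pulsewave

Pulse-wave analysis of single-sensor fingertip photoplethysmography (PPG)
across systolic-blood-pressure (SBP) groups.

PPG records pulsatile blood-volume changes with one optical sensor. The
shape of each pulse — how sharp the systolic wave is, when and how strongly
the reflected wave returns, how the energy distributes over the harmonics of
the pulse rate — changes with arterial load. `pulsewave` implements the full
analysis chain for 90-s, 500-Hz recordings, for researchers who want a
tested, reproducible reference pipeline:

* **Synthetic cohort simulator** — a physiologic beat template (Gaussian
  systolic upstroke with exponential diastolic runoff, broad reflected
  wave, dicrotic notch) with per-subject parameter draws and four SBP group
  profiles encoding monotone group trends; every downstream stage is
  testable against the simulator's ground truth.
* **Preprocessing** — zero-phase 0.5–8 Hz Butterworth band-pass, min–max
  normalization, automated artifact masking.
* **Beat segmentation** — systolic peaks via first-derivative zero
  crossings with a heart-rate-adaptive refractory period; valleys, dicrotic
  notch and reflected (P2) peak per beat.
* **Features** — 13 time-domain features (P1, P2, ΔT, Ts, Td, Ts/Td, Ss,
  Ds, Area, pulse rate, SDNN, RMSSD, PNN50), six waveform-sharpness indices
  (normalized widths at levels P1·(1 − 1/n), n = 10, 8, 6, 5, 3, 2), FFT
  harmonic amplitudes H1–H4 with ratios Hk/H1, and Welch-based pulse-rate
  variability (LF 0.04–0.15 Hz, HF 0.15–0.40 Hz, LF/HF).
* **Group statistics** — per feature: Shapiro–Wilk gate, then one-way ANOVA
  with Tukey HSD or Kruskal–Wallis with Bonferroni-adjusted Dunn pairwise
  tests; effect size ε² = H/(n−1) (η² on the ANOVA branch), classified
  small/medium/large at 0.01/0.06/0.14.

The package is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` for results, `autoplot()` for recordings and reports.

## Worked example

```r
library(pulsewave)

res <- run_pipeline(cohort_spec(n_per_group = 50, seed = 1))
head(tidy(res$report)[, c("feature", "category", "test", "statistic",
                          "p", "eps2", "effect_class")], 8)
#>   feature           category    test statistic        p  eps2 effect_class
#> 1      Ts      Time interval kruskal     105.0 1.30e-22 0.528        large
#> 2   Ts_Td      Time interval kruskal     101.6 6.95e-22 0.511        large
#> 3   H4_H1   Frequency-domain kruskal      92.8 5.51e-20 0.466        large
#> 4    s1_2 Waveform sharpness kruskal      90.8 1.50e-19 0.456        large
#> 5   H3_H1   Frequency-domain kruskal      83.3 5.91e-18 0.419        large
#> 6   H2_H1   Frequency-domain kruskal      79.0 4.98e-17 0.397        large
#> 7    s1_3 Waveform sharpness kruskal      76.7 1.54e-16 0.386        large
#> 8   s1_10 Waveform sharpness kruskal      75.4 2.95e-16 0.379        large

glance(res$report)
#>   n_features n_significant n_large n_medium n_small n_negligible
#> 1         25            22      16        5       4            0
```

Reading this: the pipeline simulated 200 subjects (50 per SBP group,
90 s at 500 Hz), extracted per-subject feature vectors, and compared each of
the 25 features across groups. Systolic-duration and sharpness features
separate the simulated groups most strongly (every group mean shifts
monotonically with SBP group by construction), the normality gate routed the
skewed feature distributions to the Kruskal–Wallis branch, and ε² values in
the "large" range reflect the cleanly encoded trends — clinical data would
show much smaller effects. `autoplot(res$report)` draws the effect-size
profile; `autoplot(rec, beats = segment_beats(rec))` shows a recording with
its fiducials.

Single stages compose with the pipe just as well:

```r
rec <- simulate_recording(morph_params(heart_rate_bpm = 75), seed = 7)
rec |> bandpass_filter() |> quality_mask() |> segment_beats() |> nn_intervals() |> hrv_time()
```

A thin CLI over the same functions ships in `inst/scripts/ppg-cohort`
(`simulate`, `extract`, `compare`, `run-all` verbs, YAML config).

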
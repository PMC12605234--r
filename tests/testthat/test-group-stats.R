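test_that("SBP group boundaries follow the clinical bins", {
  expect_identical(assign_sbp_group(c(120, 121, 139, 140, 159, 160)),
                   c(1L, 2L, 2L, 3L, 3L, 4L))
  expect_identical(assign_sbp_group(139.6), 3L)   # rounds into the 140 bin
  expect_identical(assign_sbp_group(139.4), 2L)
  expect_error(assign_sbp_group(50), "between 50 and 300")
  expect_error(assign_sbp_group(300), "between 50 and 300")
  g <- assign_sbp_group(c(95, 133, 151, 177))
  expect_identical(assign_sbp_group(c(95, 133, 151, 177)), g)  # idempotent input
})

test_that("hand-computed Kruskal-Wallis H and epsilon squared", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  H <- unname(kruskal.test(v, factor(g))$statistic)
  expect_equal(H, 27 / 7, tolerance = 1e-10)      # 3.857
  expect_equal(epsilon_squared(H, 6), 27 / 7 / 5, tolerance = 1e-10)  # 0.771
  br <- kw_brute(v, g)
  expect_equal(br$H, H, tolerance = 1e-12)
  expect_equal(br$eps2, epsilon_squared(H, 6), tolerance = 1e-12)
})

test_that("epsilon squared equals the rank-based brute force on random samples", {
  set.seed(404)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    ns <- sample(3:8, k, replace = TRUE)
    v <- round(rnorm(sum(ns)), sample(c(1, 2, Inf), 1))  # induce ties sometimes
    g <- rep(seq_len(k), ns)
    H <- suppressWarnings(unname(kruskal.test(v, factor(g))$statistic))
    if (!is.finite(H)) next
    br <- kw_brute(v, g)
    expect_lt(abs(epsilon_squared(H, length(v)) - min(br$eps2, 1)), 1e-12)
  }
})

test_that("epsilon squared edge cases and estimator variants", {
  expect_equal(epsilon_squared(0, 10), 0)
  expect_equal(epsilon_squared(5, 6), 1)         # H = n-1 saturates at 1
  # maximal two-group separation: brute force, not the naive n-1 bound
  br <- kw_brute(c(1, 2, 3, 10, 11, 12), rep(1:2, each = 3))
  expect_equal(br$H, 27 / 7, tolerance = 1e-12)
  expect_equal(br$eps2, 27 / 35, tolerance = 1e-12)
  expect_equal(epsilon_squared(3.857, 6, k = 2, method = "unbiased"),
               (3.857 - 1) / 4)
  expect_error(epsilon_squared(1, 1), "exceed 1")
})

test_that("effect classification matches the conventional thresholds", {
  expect_identical(classify_effect(c(0.005, 0.01, 0.055, 0.060, 0.139, 0.14)),
                   c("negligible", "small", "small", "medium", "medium", "large"))
})

test_that("normality gate picks ANOVA for normal and Kruskal-Wallis for skewed data", {
  set.seed(11)
  g <- rep(1:4, each = 30)
  norm_vals <- rnorm(120, mean = c(0, 0.5, 1, 1.5)[g])
  cn <- compare_feature(norm_vals, g)
  expect_identical(cn$test, "anova")
  expect_true(cn$p < 0.05)
  expect_true(all(c("pair", "p_adj") %in% names(cn$posthoc)))

  skew <- exp(rnorm(120, mean = c(0, 0.5, 1, 1.5)[g]))
  ck <- compare_feature(skew, g)
  expect_identical(ck$test, "kruskal")
  expect_true(ck$p < 0.05)
  expect_equal(ck$eps2,
               kw_brute(skew, g)$eps2, tolerance = 1e-12)
  td <- tidy(ck)
  expect_identical(td$test, "kruskal")
  expect_equal(td$p.value, ck$p)
  expect_identical(glance(ck)$n_sig_pairs > 0L, TRUE)
})

test_that("Dunn pairwise z matches the hand calculation", {
  d <- pulsewave:::dunn_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  se <- sqrt((6 * 7 / 12) * (2 / 3))
  expect_equal(abs(d$z), 3 / se, tolerance = 1e-12)
  expect_equal(d$p_adj, 2 * pnorm(-3 / se), tolerance = 1e-12)
})

test_that("degenerate inputs are flagged, not fatal", {
  g <- rep(1:4, each = 5)
  out <- compare_feature(rep(2.5, 20), g)
  expect_identical(out$flag, "zero_variance")
  expect_true(is.na(out$p))
  expect_error(compare_feature(1:6, rep(1:2, each = 3), alpha = 0.05), NA)
  expect_error(compare_feature(1:4, 1:4), ">= 2 groups")
})

test_that("null data keeps the comparison non-significant most of the time", {
  set.seed(2024)
  hits <- replicate(20, {
    v <- exp(rnorm(120))
    compare_feature(v, rep(1:4, each = 30))$p < 0.01
  })
  expect_gte(mean(!hits), 0.9)
})

test_that("cohort report has 25 ordered rows with the fixed category map", {
  coh <- simulate_cohort(cohort_spec(8, duration_s = 30, seed = 303))
  fx <- quiet(extract_features(coh$recordings))
  rep_ <- compare_cohort(fx, coh$meta)
  expect_identical(nrow(rep_), 25L)
  expect_setequal(rep_$feature, pulsewave:::comparison_features())
  e <- rep_$eps2
  expect_true(all(diff(e[!is.na(e)]) <= 1e-12))   # sorted descending
  cat_map <- setNames(rep_$category, rep_$feature)
  expect_identical(unname(cat_map["s1_10"]), "Waveform sharpness")
  expect_identical(unname(cat_map["Ts_Td"]), "Time interval")
  expect_identical(unname(cat_map["Ds"]), "Slope")
  expect_identical(unname(cat_map["RMSSD"]), "HRV")
  expect_identical(unname(cat_map["P2"]), "Peak")
  expect_identical(unname(cat_map["Area"]), "Area")
  expect_identical(unname(cat_map["H3_H1"]), "Frequency-domain")
  expect_identical(unname(cat_map["LF_HF"]), "Frequency-domain")
  # deterministic given the same feature table
  rep2 <- compare_cohort(fx, coh$meta)
  expect_identical(tidy(rep_), tidy(rep2))
  gl <- glance(rep_)
  expect_identical(gl$n_features, 25L)
})
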
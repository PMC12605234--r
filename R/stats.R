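#' Assign a systolic-blood-pressure group
#'
#' Clinical four-group coding: group 1 for SBP <= 120 mmHg, group 2 for
#' 120 < SBP <= 139, group 3 for 140 <= SBP <= 159, group 4 for SBP >= 160.
#' Non-integer values falling in the (139, 140) gap are rounded to the
#' nearest integer first. Vectorised.
#'
#' @param sbp_mmHg Systolic blood pressure(s) in mmHg, each in (50, 300).
#' @return Integer group id(s) 1--4.
#' @examples
#' assign_sbp_group(c(120, 121, 139, 140, 159, 160))
#' @export
assign_sbp_group <- function(sbp_mmHg) {
  if (!is.numeric(sbp_mmHg) || any(!is.finite(sbp_mmHg))) {
    abort("`sbp_mmHg` must be finite numeric.")
  }
  if (any(sbp_mmHg <= 50 | sbp_mmHg >= 300)) {
    abort("SBP values must lie strictly between 50 and 300 mmHg.")
  }
  s <- ifelse(sbp_mmHg > 139 & sbp_mmHg < 140, round(sbp_mmHg), sbp_mmHg)
  out <- ifelse(s <= 120, 1L, ifelse(s <= 139, 2L, ifelse(s <= 159, 3L, 4L)))
  as.integer(out)
}

#' Epsilon-squared effect size for the Kruskal-Wallis statistic
#'
#' The default ("standard") estimator is `H / (n - 1)`; the "unbiased"
#' alternative is `(H - k + 1) / (n - k)`. Clipped to `[0, 1]`.
#'
#' @param H Kruskal-Wallis statistic.
#' @param n Total sample size (> 1).
#' @param k Number of groups (needed for the unbiased form).
#' @param method `"standard"` or `"unbiased"`.
#' @return Scalar effect size in `[0, 1]`.
#' @examples
#' epsilon_squared(3.857, 6)   # ~0.771
#' @export
epsilon_squared <- function(H, n, k = NULL, method = c("standard", "unbiased")) {
  method <- match.arg(method)
  if (n <= 1) abort("`n` must exceed 1.")
  e2 <- if (method == "standard") {
    H / (n - 1)
  } else {
    if (is.null(k)) abort("`k` is required for the unbiased estimator.")
    (H - k + 1) / (n - k)
  }
  min(max(e2, 0), 1)
}

#' Classify an effect size
#'
#' Conventional epsilon-squared thresholds: below 0.01 negligible,
#' 0.01--0.06 small, 0.06--0.14 medium, 0.14 and above large.
#'
#' @param eps2 Effect size(s) in `[0, 1]`.
#' @return Character vector of labels.
#' @export
classify_effect <- function(eps2) {
  dplyr::case_when(
    is.na(eps2) ~ NA_character_,
    eps2 < 0.01 ~ "negligible",
    eps2 < 0.06 ~ "small",
    eps2 < 0.14 ~ "medium",
    TRUE ~ "large"
  )
}

# Dunn's pairwise rank comparison after Kruskal-Wallis, Bonferroni-adjusted.
# z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) * (1/n_i + 1/n_j)),
# T = sum(t^3 - t) / (12 (N - 1)) the tie correction.
dunn_test <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  lv <- sort(unique(groups))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(as.character(lv), 2)
  n_pairs <- ncol(pairs)
  purrr::map_dfr(seq_len(n_pairs), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    p <- 2 * pnorm(-abs(z))
    tibble(pair = paste(a, b, sep = "-"), z = z,
           p_adj = min(1, p * n_pairs))
  })
}

#' Compare one feature across SBP groups
#'
#' Shapiro-Wilk normality is checked per group at p < 0.05; if every group
#' passes, a one-way ANOVA with Tukey HSD post hoc is run and eta-squared
#' reported in the effect-size slot; otherwise a Kruskal-Wallis test with
#' Dunn's Bonferroni-adjusted pairwise comparisons and epsilon-squared.
#' Two-tailed, alpha 0.05.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor), >= 2 groups with >= 3
#'   values each.
#' @param eps2 Epsilon-squared estimator, `"standard"` (H/(n-1)) or
#'   `"unbiased"`.
#' @param alpha Significance level used for the post hoc summary.
#' @return An object of class `ppg_comparison` with `tidy()` and `glance()`
#'   methods: test used, statistic, p, per-group summaries, post hoc table,
#'   effect size and its classification. Degenerate input (all values
#'   identical) yields a flagged row with `p = NA` instead of an error.
#' @export
compare_feature <- function(values, groups, eps2 = c("standard", "unbiased"),
                            alpha = 0.05) {
  eps2 <- match.arg(eps2)
  ok <- complete.cases(values, groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  ns <- table(groups)
  if (length(ns) < 2L || any(ns < 3L)) {
    abort("Need >= 2 groups with >= 3 values each.")
  }
  gs <- tibble(
    group = names(ns),
    n = as.integer(ns),
    mean = as.numeric(tapply(values, groups, mean)),
    sd = as.numeric(tapply(values, groups, sd))
  )
  out <- list(group_stats = gs, eps2_method = eps2, alpha = alpha,
              flag = NA_character_)

  if (var(values) == 0) {
    out <- c(out, list(test = "none", statistic = NA_real_, p = NA_real_,
                       posthoc = tibble(), eps2 = NA_real_,
                       effect_class = NA_character_))
    out$flag <- "zero_variance"
    class(out) <- "ppg_comparison"
    return(out)
  }

  sw_p <- vapply(levels(groups), function(g) {
    v <- values[groups == g]
    if (length(unique(v)) < 3L) return(0)       # constant group: not normal
    tryCatch(shapiro.test(v)$p.value, error = function(e) 0)
  }, numeric(1))
  normal <- all(sw_p >= 0.05)

  if (normal) {
    fit <- aov(values ~ groups)
    sm <- summary(fit)[[1]]
    Fst <- sm$`F value`[1]
    p <- sm$`Pr(>F)`[1]
    ss <- sm$`Sum Sq`
    e2 <- min(max(ss[1] / sum(ss), 0), 1)       # eta-squared analogue
    tk <- TukeyHSD(fit)$groups
    posthoc <- tibble(pair = gsub(":", "-", rownames(tk)),
                      z = NA_real_, p_adj = tk[, "p adj"])
    out <- c(out, list(test = "anova", statistic = Fst, p = p,
                       posthoc = posthoc, eps2 = e2))
  } else {
    kw <- suppressWarnings(kruskal.test(values, groups))
    H <- unname(kw$statistic)
    p <- kw$p.value
    if (!is.finite(H)) {
      out <- c(out, list(test = "kruskal", statistic = NA_real_, p = NA_real_,
                         posthoc = tibble(), eps2 = NA_real_,
                         effect_class = NA_character_))
      out$flag <- "kw_undefined"
      class(out) <- "ppg_comparison"
      return(out)
    }
    posthoc <- dunn_test(values, groups)
    e2 <- epsilon_squared(H, length(values), k = nlevels(groups), method = eps2)
    out <- c(out, list(test = "kruskal", statistic = H, p = p,
                       posthoc = posthoc, eps2 = e2))
  }
  out$effect_class <- classify_effect(out$eps2)
  class(out) <- "ppg_comparison"
  out
}

#' @export
print.ppg_comparison <- function(x, ...) {
  cat(sprintf("PPG group comparison (%s): statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p))
  cat(sprintf("effect size (%s eps2/eta2) = %.4g [%s]\n",
              x$eps2_method, x$eps2, x$effect_class))
  if (!is.na(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' Per-feature SBP group comparison report
#'
#' Joins a per-subject feature table with cohort metadata, derives group ids
#' from SBP where absent, runs [compare_feature()] on each of the 25
#' comparison features, and returns one row per feature sorted by effect
#' size (descending, alphabetical on ties).
#'
#' @param features Tibble from [extract_features()] / [recording_features()].
#' @param meta Tibble with `subject_id` and `sbp_mmHg` (and optionally
#'   `group_id`).
#' @param config A [ppg_config()]; `stats$eps2` picks the effect-size
#'   estimator.
#' @return A `ppg_report` tibble: `feature`, `category`, per-group `n`,
#'   `mean`, `sd` columns, `test`, `statistic`, `p`, `eps2`, `effect_class`,
#'   `posthoc_sig_pairs`, `flag`.
#' @export
compare_cohort <- function(features, meta, config = ppg_config()) {
  cfg <- as_ppg_config(config)
  if (anyDuplicated(meta$subject_id)) abort("Duplicate subject_id in `meta`.")
  if (!"group_id" %in% names(meta)) {
    meta$group_id <- assign_sbp_group(meta$sbp_mmHg)
  }
  df <- dplyr::inner_join(features, meta, by = "subject_id")
  feats <- intersect(comparison_features(), names(df))
  rows <- purrr::map_dfr(feats, function(f) {
    cmp <- tryCatch(
      compare_feature(df[[f]], df$group_id, eps2 = cfg$stats$eps2,
                      alpha = cfg$stats$alpha),
      error = function(e) NULL
    )
    if (is.null(cmp)) {
      return(tibble(feature = f, category = feature_category(f),
                    test = NA_character_, statistic = NA_real_, p = NA_real_,
                    eps2 = NA_real_, effect_class = NA_character_,
                    posthoc_sig_pairs = NA_character_, flag = "failed"))
    }
    gs <- cmp$group_stats
    wide <- stats::setNames(
      as.list(c(gs$n, gs$mean, gs$sd)),
      c(paste0("n", gs$group), paste0("mean", gs$group), paste0("sd", gs$group))
    )
    sig <- if (nrow(cmp$posthoc)) {
      paste(cmp$posthoc$pair[cmp$posthoc$p_adj < cmp$alpha], collapse = ";")
    } else ""
    dplyr::bind_cols(
      tibble(feature = f, category = feature_category(f)),
      as_tibble(wide),
      tibble(test = cmp$test, statistic = cmp$statistic, p = cmp$p,
             eps2 = cmp$eps2, effect_class = cmp$effect_class,
             posthoc_sig_pairs = sig, flag = cmp$flag)
    )
  })
  rows <- arrange(rows, desc(.data$eps2), .data$feature)
  class(rows) <- unique(c("ppg_report", class(rows)))
  rows
}
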
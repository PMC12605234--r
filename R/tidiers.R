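#' Tidy a single feature comparison
#'
#' @param x A `ppg_comparison` from [compare_feature()].
#' @param ... Unused.
#' @return One-row tibble: `test`, `statistic`, `p.value`, `eps2`,
#'   `effect_class`, `n`, `k_groups`, `flag`.
#' @export
tidy.ppg_comparison <- function(x, ...) {
  tibble(
    test = x$test, statistic = x$statistic, p.value = x$p,
    eps2 = x$eps2, effect_class = x$effect_class,
    n = sum(x$group_stats$n), k_groups = nrow(x$group_stats),
    flag = x$flag
  )
}

#' @rdname tidy.ppg_comparison
#' @export
glance.ppg_comparison <- function(x, ...) {
  tibble(
    test = x$test, p.value = x$p, eps2 = x$eps2,
    n_sig_pairs = if (nrow(x$posthoc)) sum(x$posthoc$p_adj < x$alpha) else 0L
  )
}

#' Tidy / summarise a cohort comparison report
#'
#' `tidy()` returns the report as a plain tibble (one row per feature);
#' `glance()` summarises it: features tested, significant at alpha, and the
#' count per effect-size class.
#'
#' @param x A `ppg_report` from [compare_cohort()].
#' @param alpha Significance level for the `glance()` counts.
#' @param ... Unused.
#' @export
tidy.ppg_report <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "ppg_report")
  out
}

#' @rdname tidy.ppg_report
#' @export
glance.ppg_report <- function(x, alpha = 0.05, ...) {
  tibble(
    n_features = nrow(x),
    n_significant = sum(x$p < alpha, na.rm = TRUE),
    n_large = sum(x$effect_class == "large", na.rm = TRUE),
    n_medium = sum(x$effect_class == "medium", na.rm = TRUE),
    n_small = sum(x$effect_class == "small", na.rm = TRUE),
    n_negligible = sum(x$effect_class == "negligible", na.rm = TRUE)
  )
}
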
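#' Pipeline configuration
#'
#' Nested list of every tunable the pipeline exposes, with defaults matching
#' the study conditions: 0.5--8 Hz zero-phase Butterworth band-pass, 2 s /
#' 3.5-z quality windows, 4 Hz PRV resampling with 0.04--0.15 / 0.15--0.40 Hz
#' bands, amplitude (not power) harmonics, whole-recording aggregation, and
#' the `H/(n-1)` epsilon-squared estimator. Unknown keys are rejected.
#'
#' @param ... Named overrides, either nested lists (`filter = list(lp_hz = 5)`)
#'   or dotted keys (`"filter.lp_hz" = 5`).
#' @return A named nested list of class `ppg_config`.
#' @examples
#' cfg <- ppg_config("filter.lp_hz" = 10, stats = list(eps2 = "unbiased"))
#' cfg$filter$lp_hz
#' @export
ppg_config <- function(...) {
  defaults <- list(
    filter = list(hp_hz = 0.5, lp_hz = 8, order = 4),
    qc = list(window_s = 2, z_thresh = 3.5),
    segment = list(smooth_s = 0.025, refractory_s = NULL, prominence_frac = 0.2),
    prv = list(resample_hz = 4, lf = c(0.04, 0.15), hf = c(0.15, 0.40),
               welch_nperseg = 256, welch_overlap = 0.5),
    harmonics = list(power = FALSE, pad_factor = 4),
    aggregate = list(window_s = NULL),
    stats = list(eps2 = "standard", alpha = 0.05)
  )
  overrides <- list(...)
  if (length(overrides) && (is.null(names(overrides)) || any(names(overrides) == ""))) {
    abort("All configuration overrides must be named.")
  }
  # expand dotted keys into nested lists
  expanded <- list()
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    node <- overrides[[key]]
    for (p in rev(parts)) node <- setNames(list(node), p)
    expanded <- merge_config(expanded, node, path = character())
  }
  cfg <- merge_config(defaults, expanded, path = character(), strict = TRUE)
  structure(cfg, class = c("ppg_config", "list"))
}

merge_config <- function(base, new, path, strict = FALSE) {
  for (key in names(new)) {
    here <- paste(c(path, key), collapse = ".")
    if (strict && !key %in% names(base)) {
      abort(sprintf("Unknown configuration key `%s`.", here))
    }
    if (is.list(new[[key]]) && is.list(base[[key]])) {
      base[[key]] <- merge_config(base[[key]], new[[key]], c(path, key), strict)
    } else {
      base[[key]] <- new[[key]]
    }
  }
  base
}

as_ppg_config <- function(x) {
  if (inherits(x, "ppg_config")) return(x)
  if (is.null(x)) return(ppg_config())
  if (!is.list(x)) abort("`config` must be a `ppg_config` or a named list.")
  flat <- x
  do.call(ppg_config, flat)
}
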
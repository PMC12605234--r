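#' Construct a PPG recording tibble
#'
#' A recording is a tibble with columns `t_s` (seconds, uniform) and `ppg`
#' (amplitude, arbitrary units), optionally a logical `usable` column set by
#' [quality_mask()]. The sampling rate and subject id travel as attributes
#' but are always re-derivable from `t_s`, so plain data frames work
#' everywhere a recording does.
#'
#' @param x A data frame with columns `t_s` and `ppg`, or a numeric vector of
#'   samples (then `fs_hz` is required).
#' @param fs_hz Sampling rate; inferred from the median time step if missing.
#' @param subject_id Optional subject identifier.
#' @return A `ppg_recording` tibble.
#' @export
as_ppg_recording <- function(x, fs_hz = NULL, subject_id = NULL) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (is.null(fs_hz)) abort("`fs_hz` is required when `x` is a bare numeric vector.")
    x <- tibble(t_s = (seq_along(x) - 1) / fs_hz, ppg = as.numeric(x))
  }
  if (!is.data.frame(x) || !all(c("t_s", "ppg") %in% names(x))) {
    abort("A recording needs columns `t_s` and `ppg`.")
  }
  out <- as_tibble(x)
  if (is.null(fs_hz)) fs_hz <- infer_fs(out$t_s)
  attr(out, "fs_hz") <- fs_hz
  attr(out, "subject_id") <- subject_id %||% attr(x, "subject_id")
  class(out) <- unique(c("ppg_recording", class(out)))
  out
}

infer_fs <- function(t_s) {
  if (length(t_s) < 2L) abort("A recording needs at least two samples to infer `fs_hz`.")
  dt <- diff(t_s)
  med <- median(dt)
  if (med <= 0) abort("Time column must be strictly increasing.")
  if (max(abs(dt - med)) > 0.01 * med) {
    abort("Non-uniform sampling: max |dt - median(dt)| exceeds 1% of the median step.")
  }
  1 / med
}

# sampling rate of a recording (attribute if present, else from t_s)
#' @rdname as_ppg_recording
#' @param rec A recording data frame.
#' @export
rec_fs <- function(rec) {
  attr(rec, "fs_hz") %||% infer_fs(rec$t_s)
}

rec_subject <- function(rec) attr(rec, "subject_id") %||% NA_character_

rec_usable <- function(rec) {
  if ("usable" %in% names(rec)) rec$usable else rep(TRUE, nrow(rec))
}

# carry recording attributes through a transformed copy
rec_restamp <- function(new, old) {
  as_ppg_recording(new, fs_hz = rec_fs(old), subject_id = rec_subject(old))
}

#' Read / write a PPG recording CSV
#'
#' The on-disk dialect is a two-column CSV with header `t_s,ppg` and a
#' strictly increasing, uniform time column; the sampling rate is inferred
#' from the median time step. Files that are empty or whose time step varies
#' by more than 1% of the median are rejected.
#'
#' @param path File path.
#' @return [read_recording()] returns a `ppg_recording` tibble;
#'   [write_recording()] invisibly returns `path`.
#' @export
read_recording <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    t_s = readr::col_double(), ppg = readr::col_double()
  ), progress = FALSE)
  if (nrow(df) == 0L) abort(sprintf("Recording file '%s' is empty.", path))
  if (!identical(names(df)[1:2], c("t_s", "ppg"))) {
    abort(sprintf("Recording file '%s' must have header `t_s,ppg`.", path))
  }
  as_ppg_recording(df, subject_id = sub("\\.csv$", "", basename(path)))
}

#' @rdname read_recording
#' @param rec A recording data frame with columns `t_s` and `ppg`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(all(c("t_s", "ppg") %in% names(rec)))
  readr::write_csv(dplyr::select(as_tibble(rec), "t_s", "ppg"), path)
  invisible(path)
}

#' @export
print.ppg_recording <- function(x, ...) {
  fs <- tryCatch(rec_fs(x), error = function(e) NA_real_)
  cat(sprintf("# PPG recording: %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x), fs, nrow(x) / fs,
              if (!is.na(rec_subject(x))) paste0(", subject ", rec_subject(x)) else ""))
  NextMethod()
}
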
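#' Extract a square-ROI mean-intensity trace from a movie
#'
#' The trace value at each frame is the mean intensity over the ROI window.
#' Odd ROI sides are centred on `center`; even sides (the 6x6 ROIs used for
#' synapses) anchor their top-left corner at `center - c(2, 2)` so the
#' nominal centre sits at window position `(2, 2)` — a fixed, documented
#' convention so even ROIs are deterministic.
#'
#' @param movie A [time_lapse_movie()].
#' @param center 0-based `(y, x)` pixel coordinates of the ROI centre.
#' @param roi_side_px ROI side length in pixels (3 for DCV, 6 for synapses).
#' @return An object of class `roi_trace` with fields `center`,
#'   `roi_side_px`, `values` (one per frame) and `frame_interval_s`.
#' @export
extract_roi_trace <- function(movie, center, roi_side_px = 3) {
  stopifnot(inherits(movie, "time_lapse_movie"), length(center) == 2,
            roi_side_px >= 1)
  d <- dim(movie$frames)
  cy <- center[1] + 1   # to 1-based
  cx <- center[2] + 1
  if (roi_side_px %% 2 == 1) {
    half <- (roi_side_px - 1) / 2
    rows <- (cy - half):(cy + half)
    cols <- (cx - half):(cx + half)
  } else {
    lo <- roi_side_px / 2 - 1
    hi <- roi_side_px / 2
    rows <- (cy - lo):(cy + hi)
    cols <- (cx - lo):(cx + hi)
  }
  if (min(rows) < 1 || max(rows) > d[2] || min(cols) < 1 || max(cols) > d[3]) {
    stop(sprintf(
      "ROI of side %d at centre (y=%d, x=%d) crosses the field boundary (%dx%d)",
      roi_side_px, center[1], center[2], d[2], d[3]
    ))
  }
  sub <- movie$frames[, rows, cols, drop = FALSE]
  values <- rowMeans(matrix(sub, nrow = d[1]))
  structure(
    list(
      center = as.numeric(center),
      roi_side_px = as.integer(roi_side_px),
      values = values,
      frame_interval_s = movie$frame_interval_s,
      background = NULL
    ),
    class = "roi_trace"
  )
}

#' Construct an ROI trace directly from values
#'
#' Used when traces arrive as CSV rather than from a movie.
#'
#' @param values Intensity per frame.
#' @param frame_interval_s Frame interval (s).
#' @param center Optional 0-based `(y, x)` centre.
#' @param roi_side_px ROI side (informational).
#' @return An object of class `roi_trace`.
#' @export
roi_trace <- function(values, frame_interval_s, center = c(NA_real_, NA_real_),
                      roi_side_px = 3) {
  stopifnot(is.numeric(values), length(values) >= 1, frame_interval_s > 0)
  structure(
    list(
      center = as.numeric(center),
      roi_side_px = as.integer(roi_side_px),
      values = as.numeric(values),
      frame_interval_s = frame_interval_s,
      background = NULL
    ),
    class = "roi_trace"
  )
}

#' @export
print.roi_trace <- function(x, ...) {
  cat(sprintf(
    "<roi_trace: %dx%d px at (y=%s, x=%s), %d frames, dt = %g s>\n",
    x$roi_side_px, x$roi_side_px, format(x$center[1]), format(x$center[2]),
    length(x$values), x$frame_interval_s
  ))
  invisible(x)
}

#' Subtract a background ROI trace
#'
#' Elementwise difference; values are allowed to go negative (no flooring),
#' so that downstream normalisation sees the true signed fluctuation.
#'
#' @param trace,background [roi_trace()] objects of equal length.
#' @return A background-subtracted `roi_trace`.
#' @export
subtract_background <- function(trace, background) {
  stopifnot(inherits(trace, "roi_trace"), inherits(background, "roi_trace"))
  if (length(trace$values) != length(background$values)) {
    stop("trace and background have different lengths")
  }
  out <- trace
  out$values <- trace$values - background$values
  out$background <- background$values
  out
}

#' Normalize a trace to its baseline
#'
#' F0 is the mean of the first `n_baseline` frames; the baseline SD is the
#' sample (n-1) standard deviation of those frames. Mode `"F_over_F0"` gives
#' F/F0, mode `"dFF"` gives (F - F0)/F0.
#'
#' @param trace A [roi_trace()].
#' @param n_baseline Number of leading baseline frames (>= 2); default 10,
#'   the convention used throughout pHluorin imaging here.
#' @param mode `"dFF"` or `"F_over_F0"`.
#' @return An object of class `normalized_trace` with fields `values`, `f0`,
#'   `baseline_sd`, `mode`, `frame_interval_s`.
#' @export
normalize_trace <- function(trace, n_baseline = 10,
                            mode = c("dFF", "F_over_F0")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "roi_trace"), n_baseline >= 2)
  v <- trace$values
  if (length(v) < n_baseline + 1) {
    stop(sprintf("trace has %d frames; need at least n_baseline + 1 = %d",
                 length(v), n_baseline + 1))
  }
  f0 <- mean(v[seq_len(n_baseline)])
  if (f0 <= 0) stop("baseline F0 <= 0: normalization is uninterpretable")
  baseline_sd <- stats::sd(v[seq_len(n_baseline)])
  values <- if (mode == "F_over_F0") v / f0 else (v - f0) / f0
  structure(
    list(
      values = values,
      f0 = f0,
      baseline_sd = baseline_sd,
      mode = mode,
      frame_interval_s = trace$frame_interval_s,
      n_baseline = as.integer(n_baseline)
    ),
    class = "normalized_trace"
  )
}

#' @export
print.normalized_trace <- function(x, ...) {
  cat(sprintf(
    "<normalized_trace (%s): %d frames, F0 = %.4g, baseline SD = %.4g, dt = %g s>\n",
    x$mode, length(x$values), x$f0, x$baseline_sd, x$frame_interval_s
  ))
  invisible(x)
}

#' dFF view of a normalized trace
#'
#' Returns the values as dFF regardless of the stored mode.
#' @param ntrace A [normalize_trace()] result.
#' @return Numeric vector of dFF values.
#' @export
as_dff <- function(ntrace) {
  stopifnot(inherits(ntrace, "normalized_trace"))
  if (ntrace$mode == "dFF") ntrace$values else ntrace$values - 1
}

# ---- External interface: trace CSV -------------------------------------

#' Write a trace as CSV with columns frame, time_s, value
#'
#' @param trace A [roi_trace()] or [normalize_trace()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  v <- trace$values
  df <- data.frame(
    frame = seq_along(v) - 1L,
    time_s = (seq_along(v) - 1) * trace$frame_interval_s,
    value = v
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace CSV written by [write_trace_csv()]
#'
#' @param path CSV path with columns `frame`, `time_s`, `value`.
#' @return A [roi_trace()] (frame interval inferred from `time_s`).
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("frame", "time_s", "value") %in% names(df))) {
    stop("trace CSV must have columns frame, time_s, value")
  }
  dt <- if (nrow(df) > 1) stats::median(diff(df$time_s)) else 1
  roi_trace(df$value, dt)
}
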
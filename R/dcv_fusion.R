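#' Detect candidate fusion sites from difference images
#'
#' Fusion events appear as a rapid brightening of a punctum, so each frame in
#' the search window is compared with the pixelwise median of the three
#' preceding frames; the difference image is smoothed and spot-detected at
#' `threshold_k` robust-noise units. Detections are merged into sites across
#' frames (centres closer than `min_separation_px` are the same site), and
#' firings within `refractory_frames` of a previous firing at the same site
#' are treated as the continuation of one appearance.
#'
#' @param movie A [time_lapse_movie()].
#' @param window Search interval (s), default stimulation onset to NH4Cl
#'   onset.
#' @param threshold_k Detection threshold in robust-noise units of the
#'   smoothed difference image.
#' @param min_separation_px Minimum site separation (px).
#' @param refractory_frames Firings at the same site closer than this many
#'   frames are collapsed into one.
#' @return An object of class `candidate_sites`: a list with `centers`
#'   (data.frame of 0-based `y`, `x`) and `firings` (list of integer frame
#'   index vectors, 1-based, one vector per site).
#' @export
detect_candidate_sites <- function(movie, window = NULL, threshold_k = 5,
                                   min_separation_px = 3,
                                   refractory_frames = 2) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  if (is.null(window)) {
    if (is.null(movie$protocol) || is.null(movie$perfusion$nh4cl_window)) {
      stop("window is required when the movie carries no protocol/perfusion")
    }
    window <- c(stimulation_span(movie$protocol)[1],
                movie$perfusion$nh4cl_window[1])
  }
  check_window(window, "window")
  nf <- n_frames(movie)
  idx <- frames_in_window(nf, movie$frame_interval_s, window)
  idx <- idx[idx >= 4]   # need 3 lookback frames
  if (length(idx) == 0) stop("search window covers no usable frames")

  centers <- matrix(numeric(0), 0, 2)
  firings <- list()
  for (i in idx) {
    m3 <- median3(movie$frames[i - 3, , ], movie$frames[i - 2, , ],
                  movie$frames[i - 1, , ])
    diffim <- movie$frames[i, , ] - m3
    sm <- gaussian_smooth(diffim, 1)
    noise <- stats::mad(sm)
    thr <- stats::median(sm) + threshold_k * max(noise, 1e-9)
    peaks <- local_maxima(sm, thr)
    if (nrow(peaks) == 0) next
    keep <- nms(peaks, min_separation_px)
    peaks <- peaks[keep, , drop = FALSE]
    for (p in seq_len(nrow(peaks))) {
      y0 <- peaks[p, "y"] - 1   # to 0-based
      x0 <- peaks[p, "x"] - 1
      site <- NA_integer_
      if (nrow(centers) > 0) {
        d2 <- (centers[, 1] - y0)^2 + (centers[, 2] - x0)^2
        j <- which.min(d2)
        if (d2[j] < min_separation_px^2) site <- j
      }
      if (is.na(site)) {
        centers <- rbind(centers, c(y0, x0))
        firings[[nrow(centers)]] <- i
      } else {
        last <- firings[[site]][length(firings[[site]])]
        if (i - last > refractory_frames) {
          firings[[site]] <- c(firings[[site]], i)
        }
      }
    }
  }
  structure(
    list(
      centers = data.frame(y = centers[, 1], x = centers[, 2]),
      firings = firings,
      window = window
    ),
    class = "candidate_sites"
  )
}

#' @export
print.candidate_sites <- function(x, ...) {
  cat(sprintf("<candidate_sites: %d site(s), %d firing(s), window [%g, %g) s>\n",
              nrow(x$centers), sum(lengths(x$firings)), x$window[1], x$window[2]))
  invisible(x)
}

# Pixelwise median of three matrices without sorting.
#' @keywords internal
median3 <- function(a, b, c) {
  a + b + c - pmax(a, b, c) - pmin(a, b, c)
}

#' Detect fusion events in a normalized ROI trace
#'
#' An event opens at the first frame whose raw-equivalent fluorescence
#' reaches `F0 + sd_multiplier * SD(baseline)` after having been below; the
#' peak is the first noise-tolerant local maximum after the crossing (the
#' climb continues only while the trace keeps rising by more than one
#' baseline-SD step); rise time is measured from the last below-threshold
#' frame to the peak, and events with `rise_time_s >= max_rise_s` are
#' discarded. After a peak the detector re-arms only once the trace falls
#' back below threshold. With a noiseless baseline (SD = 0) the threshold
#' degenerates, so a floor of `1e-6 * F0` is applied.
#'
#' @param ntrace A [normalize_trace()] result.
#' @param sd_multiplier Amplitude criterion in baseline-SD units (default 2).
#' @param max_rise_s Maximum allowed rise time (s), enforced strictly.
#' @param window Optional interval (s); only events whose onset lies inside
#'   it are kept (the stimulation-to-NH4Cl interval in the DCV assay).
#' @return A data.frame of events: `onset_s` (first above-threshold frame),
#'   `peak_dff`, `rise_s`, `onset_frame` (1-based index).
#' @export
detect_fusion_events <- function(ntrace, sd_multiplier = 2, max_rise_s = 1.0,
                                 window = NULL) {
  stopifnot(inherits(ntrace, "normalized_trace"))
  v <- as_dff(ntrace)
  dt <- ntrace$frame_interval_s
  thr <- max(sd_multiplier * ntrace$baseline_sd / ntrace$f0, 1e-6)
  step <- max(ntrace$baseline_sd / ntrace$f0, 1e-9)

  onset_s <- numeric(0); peak_dff <- numeric(0); rise_s <- numeric(0)
  onset_frame <- integer(0)
  n <- length(v)
  i <- 2
  while (i <= n) {
    if (v[i] >= thr && v[i - 1] < thr) {
      peak <- climb_peak(v, i, step)
      rise <- (peak - (i - 1)) * dt
      if (rise < max_rise_s) {
        onset_s <- c(onset_s, (i - 1) * dt)   # frame i is 0-based index i-1
        peak_dff <- c(peak_dff, v[peak])
        rise_s <- c(rise_s, rise)
        onset_frame <- c(onset_frame, i)
      }
      # re-arm: skip forward until back below threshold
      i <- peak
      while (i <= n && v[i] >= thr) i <- i + 1
    } else {
      i <- i + 1
    }
  }
  ev <- data.frame(onset_s = onset_s, peak_dff = peak_dff, rise_s = rise_s,
                   onset_frame = onset_frame)
  if (!is.null(window)) {
    ev <- ev[ev$onset_s >= window[1] & ev$onset_s < window[2], , drop = FALSE]
    rownames(ev) <- NULL
  }
  ev
}

# First noise-tolerant local maximum at or after frame i: keep climbing only
# while the next frame improves on the current peak by more than `step`.
#' @keywords internal
climb_peak <- function(v, i, step) {
  peak <- i
  j <- i
  while (j < length(v) && v[j + 1] > v[peak] + step) {
    j <- j + 1
    peak <- j
  }
  peak
}

#' Full single-cell DCV fusion analysis of one movie
#'
#' Runs candidate-site detection, extracts a 3x3 ROI trace per site,
#' validates each site firing with the amplitude (F >= F0 +
#' `sd_multiplier` * SD) and rise-time (< `max_rise_s`, strict) criteria on
#' the normalized trace, counts the NH4Cl vesicle pool, and summarises the
#' cell. Validation is anchored at the firing frames so that a slow drift or
#' the fluorescence tail of a neighbouring event cannot mask or fake a
#' rapid-appearance event.
#'
#' @param movie A [time_lapse_movie()] with protocol and NH4Cl perfusion.
#' @param sd_multiplier,max_rise_s Event criteria (see
#'   [detect_fusion_events()]).
#' @param n_baseline Baseline frames for F0.
#' @param site_threshold_k Candidate-site detection threshold.
#' @return A `cell_fusion_summary` (see [summarize_cell()]) with the events
#'   data.frame (`y`, `x`, `onset_s`, `peak_dff`, `rise_s`) attached as
#'   `$events` and the sites as `$sites`.
#' @export
analyze_dcv_movie <- function(movie, sd_multiplier = 2, max_rise_s = 1.0,
                              n_baseline = 10, site_threshold_k = 5) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  if (is.null(movie$protocol) || is.null(movie$perfusion$nh4cl_window)) {
    stop("movie must carry a stimulation protocol and an NH4Cl window")
  }
  window <- c(stimulation_span(movie$protocol)[1],
              movie$perfusion$nh4cl_window[1])
  sites <- detect_candidate_sites(movie, window,
                                  threshold_k = site_threshold_k)
  dt <- movie$frame_interval_s
  ev_list <- list()
  for (s in seq_len(nrow(sites$centers))) {
    center <- c(sites$centers$y[s], sites$centers$x[s])
    tr <- tryCatch(extract_roi_trace(movie, center, 3),
                   error = function(e) NULL)
    if (is.null(tr)) next   # site hugging the border: skip
    ntr <- normalize_trace(tr, n_baseline, "dFF")
    v <- ntr$values
    thr <- max(sd_multiplier * ntr$baseline_sd / ntr$f0, 1e-6)
    step <- max(ntr$baseline_sd / ntr$f0, 1e-9)
    for (f in sites$firings[[s]]) {
      onset_s <- (f - 1) * dt
      if (onset_s < window[1] || onset_s >= window[2]) next
      peak <- climb_peak(v, f, step)
      if (v[peak] < thr) next
      rise <- (peak - (f - 1)) * dt
      if (rise >= max_rise_s) next
      ev_list[[length(ev_list) + 1]] <- data.frame(
        y = center[1], x = center[2], onset_s = onset_s,
        peak_dff = v[peak], rise_s = rise
      )
    }
  }
  events <- if (length(ev_list) > 0) {
    do.call(rbind, ev_list)
  } else {
    data.frame(y = numeric(0), x = numeric(0), onset_s = numeric(0),
               peak_dff = numeric(0), rise_s = numeric(0))
  }
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  pool <- count_pool_nh4cl(movie)
  out <- summarize_cell(events, pool, movie$protocol)
  out$sites <- sites
  out
}

#' Summarise DCV exocytosis for one cell
#'
#' @param events Data.frame of fusion events with at least `onset_s`.
#' @param pool Total vesicle pool (NH4Cl puncta count). The fused-fraction
#'   denominator is this total pool; `denominator = "remaining"` instead
#'   divides by `pool - n_events`, the pool left after stimulation.
#' @param protocol Optional [stimulation_protocol()]; the cumulative curve
#'   is aligned to its first burst onset.
#' @param denominator `"total"` (default) or `"remaining"`.
#' @return An object of class `cell_fusion_summary`: `n_events`, `pool`,
#'   `fused_fraction` (NA with a `quality_flag` when the denominator is
#'   degenerate), `cumulative` (data.frame `time_s`, `count`).
#' @export
summarize_cell <- function(events, pool, protocol = NULL,
                           denominator = c("total", "remaining")) {
  denominator <- match.arg(denominator)
  pool <- as.integer(pool)
  stopifnot(pool >= 0)
  n_events <- nrow(events)
  denom <- if (denominator == "total") pool else pool - n_events
  quality_flag <- NULL
  if (denom <= 0) {
    fused_fraction <- if (n_events == 0 && pool == 0) 0 else NA_real_
    if (is.na(fused_fraction)) {
      quality_flag <- sprintf("fused fraction undefined: %d events over denominator %d",
                              n_events, denom)
    }
  } else {
    fused_fraction <- n_events / denom
    if (fused_fraction > 1) {
      quality_flag <- sprintf("fused fraction %.3f exceeds 1", fused_fraction)
    }
  }
  t0 <- if (!is.null(protocol)) protocol$burst_onsets[1] else 0
  times <- sort(events$onset_s) - t0
  cumulative <- data.frame(time_s = c(0, times),
                           count = c(0, seq_len(n_events)))
  structure(
    list(
      n_events = n_events,
      pool = pool,
      fused_fraction = fused_fraction,
      cumulative = cumulative,
      denominator = denominator,
      quality_flag = quality_flag,
      events = events
    ),
    class = "cell_fusion_summary"
  )
}

#' @export
print.cell_fusion_summary <- function(x, ...) {
  cat(sprintf(
    "<cell_fusion_summary: %d events, pool %d, fused fraction %s>\n",
    x$n_events, x$pool,
    if (is.na(x$fused_fraction)) "undefined" else sprintf("%.3f", x$fused_fraction)
  ))
  if (!is.null(x$quality_flag)) cat("  flag:", x$quality_flag, "\n")
  invisible(x)
}

#' @export
plot.cell_fusion_summary <- function(x, ...) {
  graphics::plot(
    x$cumulative$time_s, x$cumulative$count, type = "s",
    xlab = "time from stimulation onset (s)", ylab = "cumulative fusion events",
    main = sprintf("%d events / pool %d", x$n_events, x$pool), ...
  )
  invisible(x)
}

#' Percent change between two groups of cell summaries
#'
#' Reduction of condition B relative to condition A,
#' `100 * (mean_A - mean_B) / mean_A`, for the mean event count and the mean
#' fused fraction.
#'
#' @param summaries_a,summaries_b Lists of `cell_fusion_summary` objects
#'   (condition A is the reference, e.g. control).
#' @return List with `pct_change_events`, `pct_change_fraction` (NA with a
#'   flag when a reference mean is zero), and the four group means.
#' @export
compare_conditions <- function(summaries_a, summaries_b) {
  stopifnot(length(summaries_a) > 0, length(summaries_b) > 0)
  mean_of <- function(xs, field) {
    mean(vapply(xs, function(s) as.numeric(s[[field]]), numeric(1)), na.rm = TRUE)
  }
  ev_a <- mean_of(summaries_a, "n_events")
  ev_b <- mean_of(summaries_b, "n_events")
  fr_a <- mean_of(summaries_a, "fused_fraction")
  fr_b <- mean_of(summaries_b, "fused_fraction")
  pct <- function(a, b) if (a == 0) NA_real_ else 100 * (a - b) / a
  out <- list(
    pct_change_events = pct(ev_a, ev_b),
    pct_change_fraction = pct(fr_a, fr_b),
    mean_events_a = ev_a, mean_events_b = ev_b,
    mean_fraction_a = fr_a, mean_fraction_b = fr_b
  )
  if (is.na(out$pct_change_events) || is.na(out$pct_change_fraction)) {
    out$quality_flag <- "reference mean is zero: percent change undefined"
  }
  out
}
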
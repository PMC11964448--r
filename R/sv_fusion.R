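#' Identify synapse ROIs from the NH4Cl dequenching response
#'
#' Synapses are found as puncta in the difference between the mean NH4Cl
#' plateau image and the mean of the frames immediately preceding the NH4Cl
#' window (default the last 10), then one 6x6 ROI trace is extracted per
#' punctum. Sites too close to the field border for a 6x6 window are
#' dropped.
#'
#' @param movie A [time_lapse_movie()].
#' @param perfusion A [perfusion_schedule()] with an NH4Cl window.
#' @param n_pre_frames Frames before the window used as the reference image.
#' @param ... Passed to [detect_puncta()].
#' @return List of 6x6 [roi_trace()] objects (centres attached).
#' @export
identify_synapse_rois <- function(movie, perfusion = movie$perfusion,
                                  n_pre_frames = 10, ...) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  if (is.null(perfusion) || is.null(perfusion$nh4cl_window)) {
    stop("no NH4Cl window in the perfusion schedule")
  }
  w <- perfusion$nh4cl_window
  nf <- n_frames(movie)
  dt <- movie$frame_interval_s
  plateau <- nh4cl_plateau_frames(nf, dt, w)
  pre_all <- which((seq_len(nf) - 1) * dt < w[1])
  if (length(plateau) < 1 || length(pre_all) < 1) {
    stop("NH4Cl window leaves no plateau or pre-window frames")
  }
  pre <- utils::tail(pre_all, n_pre_frames)
  proj <- apply(movie$frames[plateau, , , drop = FALSE], c(2, 3), mean) -
    apply(movie$frames[pre, , , drop = FALSE], c(2, 3), mean)
  centers <- detect_puncta(proj, ...)
  out <- list()
  for (i in seq_len(nrow(centers))) {
    tr <- tryCatch(
      extract_roi_trace(movie, c(centers$y[i], centers$x[i]), 6),
      error = function(e) NULL
    )
    if (!is.null(tr)) out[[length(out) + 1]] <- tr
  }
  out
}

#' Classify a synapse as active
#'
#' Active means the maximum dFF during the stimulation window reaches
#' `sd_multiplier` times the baseline noise expressed in dFF units
#' (`baseline_sd / F0`); the comparison is inclusive (>=).
#'
#' @param ntrace A [normalize_trace()] result in dFF mode.
#' @param stim_window Stimulation interval (s).
#' @param sd_multiplier Threshold multiplier (default 3).
#' @return Logical.
#' @export
classify_active <- function(ntrace, stim_window, sd_multiplier = 3) {
  stopifnot(inherits(ntrace, "normalized_trace"))
  if (ntrace$mode != "dFF") stop("classify_active expects a dFF trace")
  check_window(stim_window, "stim_window")
  idx <- frames_in_window(length(ntrace$values), ntrace$frame_interval_s,
                          stim_window)
  if (length(idx) == 0) stop("stimulation window covers no frames")
  max(ntrace$values[idx]) >= sd_multiplier * ntrace$baseline_sd / ntrace$f0
}

#' Synaptic-vesicle fused fraction of one synapse
#'
#' Ratio of the maximum dFF during stimulation to the maximum dFF during
#' NH4Cl dequenching (the total recycling pool signal). The stimulation
#' maximum is searched over the window plus a 2 s margin so that a peak
#' falling on the first post-stimulus frame is not lost to frame
#' quantization.
#'
#' @param ntrace A [normalize_trace()] result in dFF mode.
#' @param stim_window,nh4cl_window Intervals (s).
#' @param stim_margin_s Margin added after the stimulation window (s).
#' @return Fused fraction (unitless).
#' @export
sv_fused_fraction <- function(ntrace, stim_window, nh4cl_window,
                              stim_margin_s = 2) {
  stopifnot(inherits(ntrace, "normalized_trace"))
  check_window(stim_window, "stim_window")
  check_window(nh4cl_window, "nh4cl_window")
  v <- as_dff(ntrace)
  n <- length(v)
  dt <- ntrace$frame_interval_s
  stim_idx <- frames_in_window(n, dt, c(stim_window[1],
                                        stim_window[2] + stim_margin_s))
  nh_idx <- frames_in_window(n, dt, nh4cl_window)
  if (length(stim_idx) == 0 || length(nh_idx) == 0) {
    stop("stimulation or NH4Cl window covers no frames")
  }
  dmax <- max(v[nh_idx])
  if (dmax <= 0) stop("no NH4Cl dequenching response (dF_NH4Cl <= 0)")
  max(v[stim_idx]) / dmax
}

#' Fit the endocytosis decay time constant
#'
#' Least-squares fit of `A * exp(-t/tau) + C` to the dFF trace over
#' `decay_window_s` seconds after the end of stimulation, t measured from
#' `post_stim_start`. The offset C absorbs any plateau from incomplete
#' retrieval.
#'
#' @param ntrace A [normalize_trace()] result.
#' @param post_stim_start Start of the decay window (s), normally the end of
#'   field stimulation.
#' @param decay_window_s Length of the fitted window (s), default 60.
#' @return List with `tau_s` (NA on failure), `A`, `C`, `converged`.
#' @export
fit_endocytosis_tau <- function(ntrace, post_stim_start, decay_window_s = 60) {
  stopifnot(inherits(ntrace, "normalized_trace"), decay_window_s > 0)
  v <- as_dff(ntrace)
  idx <- frames_in_window(length(v), ntrace$frame_interval_s,
                          c(post_stim_start, post_stim_start + decay_window_s),
                          closed = TRUE)
  if (length(idx) < 6) stop("need at least 6 samples in the decay window")
  t <- (idx - 1) * ntrace$frame_interval_s - post_stim_start
  y <- v[idx]
  failed <- list(tau_s = NA_real_, A = NA_real_, C = NA_real_,
                 converged = FALSE)
  if (y[1] <= y[length(y)] || max(y) <= 0) return(failed)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-t / tau) + C,
      start = list(A = max(y[1] - min(y), 1e-3), C = min(y),
                   tau = decay_window_s / 4),
      lower = c(A = 0, C = -Inf, tau = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed)
  cf <- stats::coef(fit)
  list(tau_s = unname(cf["tau"]), A = unname(cf["A"]), C = unname(cf["C"]),
       converged = TRUE)
}

#' Pool active synapses per neuron
#'
#' Each active synapse trace is rescaled from baseline (0) to its NH4Cl
#' maximum (1), then averaged across active synapses; fused fractions are
#' averaged alongside.
#'
#' @param ntraces List of [normalize_trace()] results (dFF), one per
#'   synapse.
#' @param active Logical vector: which synapses are active.
#' @param fused_fractions Numeric vector of per-synapse fused fractions.
#' @param nh4cl_window NH4Cl interval (s) used for the rescaling maximum.
#' @return List with `mean_trace` (rescaled mean over active synapses; NULL
#'   when none are active), `mean_fused_fraction` (NA when none active),
#'   `n_active`.
#' @export
average_active_synapses <- function(ntraces, active, fused_fractions,
                                    nh4cl_window) {
  stopifnot(length(ntraces) == length(active),
            length(active) == length(fused_fractions))
  check_window(nh4cl_window, "nh4cl_window")
  if (!any(active)) {
    return(list(mean_trace = NULL, mean_fused_fraction = NA_real_,
                n_active = 0L))
  }
  act <- which(active)
  rescaled <- lapply(act, function(i) {
    v <- as_dff(ntraces[[i]])
    idx <- frames_in_window(length(v), ntraces[[i]]$frame_interval_s,
                            nh4cl_window)
    m <- max(v[idx])
    if (m <= 0) stop(sprintf("synapse %d has no NH4Cl response", i))
    v / m
  })
  list(
    mean_trace = Reduce(`+`, rescaled) / length(rescaled),
    mean_fused_fraction = mean(fused_fractions[act]),
    n_active = length(act)
  )
}

#' Full SypHy analysis of a list of synapse traces
#'
#' Normalizes each trace, classifies activity, computes per-synapse fused
#' fractions and the per-neuron pooled summary, and fits the endocytosis
#' decay on the pooled active-synapse mean.
#'
#' @param traces List of [roi_trace()] objects.
#' @param stim_window,nh4cl_window Intervals (s).
#' @param n_baseline Baseline frames for F0.
#' @param sd_multiplier Activity criterion (default 3).
#' @return List with `records` (per-synapse: `active`, `fused_fraction`),
#'   `pooled` (see [average_active_synapses()]), `tau_s` from the pooled
#'   decay fit.
#' @export
analyze_sv_traces <- function(traces, stim_window, nh4cl_window,
                              n_baseline = 10, sd_multiplier = 3) {
  ntraces <- lapply(traces, normalize_trace, n_baseline = n_baseline,
                    mode = "dFF")
  active <- vapply(ntraces, classify_active, logical(1),
                   stim_window = stim_window, sd_multiplier = sd_multiplier)
  fractions <- vapply(ntraces, function(nt) {
    tryCatch(sv_fused_fraction(nt, stim_window, nh4cl_window),
             error = function(e) NA_real_)
  }, numeric(1))
  pooled <- average_active_synapses(ntraces, active, fractions, nh4cl_window)
  tau_s <- NA_real_
  if (!is.null(pooled$mean_trace)) {
    mean_nt <- structure(
      list(values = pooled$mean_trace, f0 = 1, baseline_sd = 0, mode = "dFF",
           frame_interval_s = ntraces[[1]]$frame_interval_s,
           n_baseline = as.integer(n_baseline)),
      class = "normalized_trace"
    )
    fit <- tryCatch(
      fit_endocytosis_tau(mean_nt, post_stim_start = stim_window[2]),
      error = function(e) list(tau_s = NA_real_)
    )
    tau_s <- fit$tau_s
  }
  list(
    records = data.frame(synapse = seq_along(traces), active = active,
                         fused_fraction = fractions),
    pooled = pooled,
    tau_s = tau_s
  )
}
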
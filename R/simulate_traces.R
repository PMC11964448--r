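#' Simulate SypHy synapse traces with ground truth
#'
#' Each synapse trace starts at `baseline_level`. Active synapses rise by
#' `stim_amplitude * baseline_level` during the stimulation epoch and decay
#' exponentially with `tau_s` afterwards (endocytic re-acidification); all
#' synapses rise by `nh4cl_amplitude * baseline_level` during the NH4Cl
#' window. The programmed fused fraction is therefore
#' `stim_amplitude / nh4cl_amplitude` exactly.
#'
#' @param n_synapses Number of synapse traces.
#' @param active_fraction Fraction of synapses that respond to stimulation.
#' @param stim_amplitude,nh4cl_amplitude Response amplitudes in dFF units
#'   (fractions of baseline); both must be >= 0.
#' @param tau_s Endocytosis decay time constant (s).
#' @param noise_sd Additive Gaussian noise SD (intensity counts).
#' @param frame_interval_s Frame interval (s).
#' @param duration_s Recording length (s).
#' @param protocol A [stimulation_protocol()]; default 5 s at 40 Hz.
#' @param perfusion A [perfusion_schedule()] with an NH4Cl window.
#' @param baseline_level Baseline intensity (counts).
#' @param seed Integer seed.
#' @return List with `traces` (list of [roi_trace()]), `protocol`,
#'   `perfusion` and `truth` (`active` logical vector, `tau_s`,
#'   `fused_fraction`).
#' @export
simulate_syphy_traces <- function(n_synapses = 40,
                                  active_fraction = 0.6,
                                  stim_amplitude = 0.3,
                                  nh4cl_amplitude = 1.0,
                                  tau_s = 15,
                                  noise_sd = 0,
                                  frame_interval_s = 0.5,
                                  duration_s = 120,
                                  protocol = protocol_preset("SV_HFS"),
                                  perfusion = perfusion_schedule(nh4cl_window = c(95, 115)),
                                  baseline_level = 100,
                                  seed = 1) {
  stopifnot(active_fraction >= 0, active_fraction <= 1, tau_s > 0)
  if (stim_amplitude < 0 || nh4cl_amplitude < 0) {
    stop("amplitudes must be non-negative")
  }
  if (is.null(perfusion$nh4cl_window)) stop("perfusion must include an NH4Cl window")
  seeds <- derive_seeds(seed, 2)
  nf <- ceiling(duration_s / frame_interval_s)
  times <- (seq_len(nf) - 1) * frame_interval_s
  span <- stimulation_span(protocol)
  w <- perfusion$nh4cl_window

  set.seed(seeds[1])
  n_active <- round(active_fraction * n_synapses)
  active <- rep(FALSE, n_synapses)
  if (n_active > 0) active[sample(n_synapses, n_active)] <- TRUE

  shape <- numeric(nf)                       # stimulation response, dFF units
  in_stim <- times >= span[1] & times < span[2]
  post <- times >= span[2]
  shape[in_stim] <- (times[in_stim] - span[1]) / diff(span)   # linear loading
  shape[post] <- exp(-(times[post] - span[2]) / tau_s)
  nh <- as.numeric(times >= w[1] & times < w[2])

  set.seed(seeds[2])
  traces <- lapply(seq_len(n_synapses), function(i) {
    v <- baseline_level * (1 +
      (if (active[i]) stim_amplitude * shape else 0) + nh4cl_amplitude * nh)
    if (noise_sd > 0) v <- v + stats::rnorm(nf, 0, noise_sd)
    roi_trace(v, frame_interval_s, roi_side_px = 6)
  })
  truth <- structure(
    list(active = active, tau_s = tau_s,
         fused_fraction = stim_amplitude / nh4cl_amplitude,
         pool_size = n_synapses),
    class = "ground_truth"
  )
  list(traces = traces, protocol = protocol, perfusion = perfusion, truth = truth)
}

#' Simulate an ER-GCaMP6-150 fluorescence trace from a concentration profile
#'
#' Forward model of the ER Ca2+ calibration: at each frame the fluorescence
#' is `fmax_level * r(t)` where `r(t)` is the resting-to-maximal ratio that
#' the calibration formula maps back to `conc_profile_uM(t)` (the exact
#' algebraic inverse). After `ionomycin_onset` the indicator saturates at
#' `fmax_level`.
#'
#' @param conc_profile_uM Non-negative ER Ca2+ concentrations (µM), one per
#'   frame.
#' @param calib An [er_calibration()].
#' @param fmax_level Saturated fluorescence level (counts).
#' @param noise_sd Additive Gaussian noise SD (counts).
#' @param ionomycin_onset Time (s) at which ionomycin saturates the
#'   indicator, or NULL.
#' @param frame_interval_s Frame interval (s).
#' @param seed Integer seed.
#' @return List with `trace` (a [roi_trace()]), `perfusion` and `truth`
#'   (`concentration_uM` profile).
#' @export
simulate_er_gcamp_trace <- function(conc_profile_uM, calib = er_calibration(),
                                    fmax_level = 1000, noise_sd = 0,
                                    ionomycin_onset = NULL,
                                    frame_interval_s = 1, seed = 1) {
  if (any(conc_profile_uM < 0)) stop("concentrations must be >= 0")
  nf <- length(conc_profile_uM)
  times <- (seq_len(nf) - 1) * frame_interval_s
  r <- ratio_for_concentration(conc_profile_uM, calib)
  v <- fmax_level * r
  if (!is.null(ionomycin_onset)) v[times >= ionomycin_onset] <- fmax_level
  if (noise_sd > 0) {
    set.seed(derive_seeds(seed, 1))
    v <- v + stats::rnorm(nf, 0, noise_sd)
  }
  truth <- structure(
    list(concentration_uM = conc_profile_uM,
         true_concentration_uM = conc_profile_uM[1]),
    class = "ground_truth"
  )
  list(
    trace = roi_trace(v, frame_interval_s, roi_side_px = 6),
    perfusion = perfusion_schedule(ionomycin_onset = ionomycin_onset),
    truth = truth
  )
}

#' Simulate a normalized ER refill trace after caffeine washout
#'
#' Pre-washout frames sit at 1 (the pre-caffeine store level). At washout
#' (t = 0) the normalized signal has been depleted by `depletion_depth` and
#' refills as `1 - depletion_depth * exp(-t / refill_tau_s)` — SERCA-driven
#' store refilling. `refill_tau_s = 0` is the immediate-recovery limit.
#'
#' @param depletion_depth Depth of depletion in [0, 1] (1 = fully emptied).
#' @param refill_tau_s Refill time constant (s), >= 0.
#' @param duration_s Post-washout duration (s).
#' @param frame_interval_s Frame interval (s).
#' @param noise_sd Additive Gaussian noise SD (normalized units).
#' @param baseline_s Pre-washout baseline length (s).
#' @param seed Integer seed.
#' @return List with `time_s`, `values` (normalized), `washout_time_s`
#'   (always `baseline_s`) and `truth` (depth, tau).
#' @export
simulate_caffeine_refill <- function(depletion_depth, refill_tau_s,
                                     duration_s = 300, frame_interval_s = 1,
                                     noise_sd = 0, baseline_s = 10, seed = 1) {
  stopifnot(depletion_depth >= 0, depletion_depth <= 1, refill_tau_s >= 0)
  t <- seq(0, baseline_s + duration_s, by = frame_interval_s)
  tp <- t - baseline_s                       # time since washout
  v <- rep(1, length(t))
  post <- tp >= 0
  if (refill_tau_s == 0) {
    v[tp == 0] <- 1 - depletion_depth
  } else {
    v[post] <- 1 - depletion_depth * exp(-tp[post] / refill_tau_s)
  }
  if (noise_sd > 0) {
    set.seed(derive_seeds(seed, 1))
    v <- v + stats::rnorm(length(v), 0, noise_sd)
  }
  truth <- structure(
    list(depletion_depth = depletion_depth, refill_tau_s = refill_tau_s),
    class = "ground_truth"
  )
  list(time_s = t, values = v, washout_time_s = baseline_s, truth = truth)
}

#' Simulate a FRAP trace with ground truth
#'
#' `n_prebleach` frames at baseline, then post-bleach frames following
#' `F0 * ((1 - bleach_depth) + bleach_depth * mobile_fraction *
#' (1 - exp(-t / tau_s)))` with the post-bleach clock starting at the first
#' post-bleach frame. Defaults mirror the mCherry-ER3 protocol: 10 prebleach
#' frames every 8.5 s, 300 s of recovery.
#'
#' @param mobile_fraction Mobile fraction in [0, 1].
#' @param tau_s Recovery time constant (s).
#' @param bleach_depth Bleach depth in [0, 1] (1 = complete bleach).
#' @param n_prebleach Number of prebleach frames.
#' @param frame_interval_s Frame interval (s).
#' @param duration_s Post-bleach duration (s).
#' @param noise_sd Additive Gaussian noise SD (counts).
#' @param baseline_level Prebleach intensity (counts).
#' @param seed Integer seed.
#' @return List with `trace` (a [frap_trace()]) and `truth`
#'   (`true_mobile_fraction`, `true_tau_s`, `bleach_depth`).
#' @export
simulate_frap_trace <- function(mobile_fraction, tau_s = 30, bleach_depth = 1,
                                n_prebleach = 10, frame_interval_s = 8.5,
                                duration_s = 300, noise_sd = 0,
                                baseline_level = 100, seed = 1) {
  stopifnot(mobile_fraction >= 0, mobile_fraction <= 1,
            bleach_depth >= 0, bleach_depth <= 1, tau_s > 0)
  n_post <- ceiling(duration_s / frame_interval_s) + 1
  t_post <- (seq_len(n_post) - 1) * frame_interval_s
  post <- baseline_level * ((1 - bleach_depth) +
    bleach_depth * mobile_fraction * (1 - exp(-t_post / tau_s)))
  v <- c(rep(baseline_level, n_prebleach), post)
  if (noise_sd > 0) {
    set.seed(derive_seeds(seed, 1))
    v <- v + stats::rnorm(length(v), 0, noise_sd)
  }
  truth <- structure(
    list(true_mobile_fraction = mobile_fraction, true_tau_s = tau_s,
         bleach_depth = bleach_depth),
    class = "ground_truth"
  )
  list(trace = frap_trace(v, frame_interval_s, n_prebleach), truth = truth)
}

#' Simulate nested group/culture measurements
#'
#' value = group mean + culture offset + Gaussian residual: the hierarchical
#' structure assumed by the nested-culture ANOVA (neurons nested in
#' independent cultures, culture as a fixed covariate). The design is
#' balanced: `n_per_cell` observations for every group x culture cell.
#'
#' @param group_means Named numeric vector of group means (>= 2 groups for
#'   comparisons; a single group is allowed for null simulations).
#' @param culture_offsets Numeric vector of per-culture offsets (>= 1).
#' @param residual_sd Residual SD (>= 0).
#' @param n_per_cell Observations per group x culture cell.
#' @param seed Integer seed.
#' @return A data.frame with columns `value`, `group`, `culture`.
#' @export
simulate_grouped_measurements <- function(group_means, culture_offsets,
                                          residual_sd, n_per_cell, seed = 1) {
  stopifnot(length(group_means) >= 1, length(culture_offsets) >= 1,
            residual_sd >= 0, n_per_cell >= 1)
  if (is.null(names(group_means))) {
    names(group_means) <- paste0("g", seq_along(group_means))
  }
  set.seed(derive_seeds(seed, 1))
  grid <- expand.grid(
    group = names(group_means),
    culture = paste0("c", seq_along(culture_offsets)),
    rep = seq_len(n_per_cell),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  mu <- group_means[grid$group] + culture_offsets[match(grid$culture,
    paste0("c", seq_along(culture_offsets)))]
  data.frame(
    value = mu + stats::rnorm(nrow(grid), 0, residual_sd),
    group = grid$group,
    culture = grid$culture,
    stringsAsFactors = FALSE
  )
}
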
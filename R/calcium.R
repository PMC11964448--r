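#' ER-GCaMP6-150 calibration constants
#'
#' Constants of the Hill-type calibration mapping the resting-to-maximal
#' fluorescence ratio of an ER-lumen Ca2+ indicator to a free Ca2+
#' concentration: the affinity constant Kd (150 µM), the dynamic range
#' Rf = Fmax/Fmin (45), and the Hill coefficient n (1.6).
#'
#' @param kd_uM Affinity constant (µM), > 0.
#' @param rf Dynamic range, > 1.
#' @param hill_n Hill coefficient, > 0.
#' @return An object of class `er_calibration`.
#' @export
er_calibration <- function(kd_uM = 150, rf = 45, hill_n = 1.6) {
  stopifnot(kd_uM > 0, rf > 1, hill_n > 0)
  structure(list(kd_uM = kd_uM, rf = rf, hill_n = hill_n),
            class = "er_calibration")
}

#' @export
print.er_calibration <- function(x, ...) {
  cat(sprintf("<er_calibration: Kd = %g uM, Rf = %g, Hill n = %g>\n",
              x$kd_uM, x$rf, x$hill_n))
  invisible(x)
}

#' ER Ca2+ concentration from a fluorescence ratio
#'
#' Inverts the indicator's Hill saturation curve:
#' \deqn{[Ca]_{ER} = K_d \left(\frac{r - 1/R_f}{1 - r}\right)^{1/n}}
#' with `r = Fr/Fmax`. The exponent 1/n applies to the whole bracket — the
#' standard Hill inversion, and the only reading under which Kd is the
#' half-saturation point (the bracket equals 1 exactly when the indicator is
#' half-way between its floor 1/Rf and ceiling 1). The function is strictly
#' increasing on its domain and returns 0 at `r = 1/Rf`.
#'
#' @param fr_over_fmax Ratio(s) in `[1/Rf, 1)`.
#' @param calib An [er_calibration()].
#' @return Concentration(s) in µM.
#' @export
er_concentration <- function(fr_over_fmax, calib = er_calibration()) {
  r <- fr_over_fmax
  if (any(r >= 1)) stop("ratio saturated: Fr/Fmax must be < 1")
  if (any(r < 1 / calib$rf)) {
    stop(sprintf("ratio below dynamic range: Fr/Fmax must be >= 1/Rf = %.6g",
                 1 / calib$rf))
  }
  bracket <- (r - 1 / calib$rf) / (1 - r)
  calib$kd_uM * bracket^(1 / calib$hill_n)
}

#' Fluorescence ratio expected at a given ER Ca2+ concentration
#'
#' Algebraic inverse of [er_concentration()]: with `B = (conc/Kd)^n`,
#' `r = (B + 1/Rf) / (1 + B)`. Round-trips with [er_concentration()] to
#' better than 1e-9 relative.
#'
#' @param conc_uM Concentration(s) in µM, >= 0.
#' @param calib An [er_calibration()].
#' @return Ratio(s) in `[1/Rf, 1)`.
#' @export
ratio_for_concentration <- function(conc_uM, calib = er_calibration()) {
  if (any(conc_uM < 0)) stop("concentrations must be >= 0")
  b <- (conc_uM / calib$kd_uM)^calib$hill_n
  (b + 1 / calib$rf) / (1 + b)
}

#' Estimate resting ER Ca2+ from a trace with an ionomycin saturation
#'
#' Fr is the mean fluorescence over the resting window; Fmax is the mean
#' over the ionomycin plateau, taken as the last 50% of the ionomycin window
#' to skip the wash-in. No pH correction is applied to Fmax. Because the
#' estimate uses only the ratio Fr/Fmax it is invariant to any global gain
#' on the trace.
#'
#' @param trace A [roi_trace()] (raw fluorescence).
#' @param rest_window,ionomycin_window Time intervals (s), each covering at
#'   least 3 frames.
#' @param calib An [er_calibration()].
#' @return Estimated concentration (µM).
#' @export
estimate_er_calcium <- function(trace, rest_window, ionomycin_window,
                                calib = er_calibration()) {
  stopifnot(inherits(trace, "roi_trace"))
  check_window(rest_window, "rest_window")
  check_window(ionomycin_window, "ionomycin_window")
  n <- length(trace$values)
  dt <- trace$frame_interval_s
  rest_idx <- frames_in_window(n, dt, rest_window)
  iono_all <- frames_in_window(n, dt, ionomycin_window)
  if (length(rest_idx) < 3 || length(iono_all) < 3) {
    stop("rest and ionomycin windows must each cover at least 3 frames")
  }
  plateau <- frames_in_window(n, dt, c(
    ionomycin_window[1] + diff(ionomycin_window) / 2, ionomycin_window[2]
  ))
  if (length(plateau) == 0) plateau <- iono_all
  fr <- mean(trace$values[rest_idx])
  fmax <- mean(trace$values[plateau])
  if (fmax <= fr) stop("Fmax <= Fr: no ionomycin saturation response")
  er_concentration(fr / fmax, calib)
}

#' Peak and area of a caffeine-evoked cytosolic Ca2+ response
#'
#' @param ntrace A [normalize_trace()] result in dFF mode.
#' @param caffeine_window Time interval (s); integration uses the closed
#'   interval so that abutting windows tile additively.
#' @return List with `peak_dff` and `auc` (dFF * s, trapezoidal).
#' @export
caffeine_cyto_response <- function(ntrace, caffeine_window) {
  stopifnot(inherits(ntrace, "normalized_trace"))
  check_window(caffeine_window, "caffeine_window")
  v <- as_dff(ntrace)
  idx <- frames_in_window(length(v), ntrace$frame_interval_s, caffeine_window,
                          closed = TRUE)
  if (length(idx) == 0) stop("caffeine window covers no frames")
  t <- (idx - 1) * ntrace$frame_interval_s
  list(
    peak_dff = max(v[idx]),
    auc = if (length(idx) > 1) pracma::trapz(t, v[idx]) else 0
  )
}

#' ER refill recovery fraction at a time after caffeine washout
#'
#' recovery(t) = (F(washout + t) - depleted) / (baseline - depleted), with
#' linear interpolation between frames. The conventional readout time is
#' T = 190 s after washout.
#'
#' @param values Normalized fluorescence values.
#' @param time_s Time stamps (s) of `values`.
#' @param washout_time Caffeine washout time (s) on the `time_s` axis.
#' @param baseline_level Pre-caffeine (full-store) normalized level.
#' @param depleted_level Normalized level at full depletion.
#' @param t_eval Evaluation time after washout (s); default 190.
#' @return Recovery fraction (0 = still depleted, 1 = fully refilled).
#' @export
er_refill_recovery <- function(values, time_s, washout_time,
                               baseline_level = 1, depleted_level = 0,
                               t_eval = 190) {
  stopifnot(length(values) == length(time_s))
  if (baseline_level <= depleted_level) {
    stop("baseline_level must exceed depleted_level")
  }
  target <- washout_time + t_eval
  if (target < min(time_s) || target > max(time_s)) {
    stop(sprintf("t_eval = %g s falls outside the recording", t_eval))
  }
  f <- stats::approx(time_s, values, xout = target)$y
  (f - depleted_level) / (baseline_level - depleted_level)
}

#' Area under a stimulus-evoked Ca2+ response
#'
#' Trapezoidal integral of dFF from the stimulation onset to the window end
#' plus `post_margin_s` (closed interval).
#'
#' @param ntrace A [normalize_trace()] result.
#' @param stim_window Stimulation interval (s).
#' @param post_margin_s Extra integration time after the window end (s).
#' @return AUC in dFF * s.
#' @export
stim_response_auc <- function(ntrace, stim_window, post_margin_s = 0) {
  stopifnot(inherits(ntrace, "normalized_trace"), post_margin_s >= 0)
  check_window(stim_window, "stim_window")
  v <- as_dff(ntrace)
  idx <- frames_in_window(length(v), ntrace$frame_interval_s,
                          c(stim_window[1], stim_window[2] + post_margin_s),
                          closed = TRUE)
  if (length(idx) == 0) stop("stimulation window covers no frames")
  if (length(idx) < 2) return(0)
  t <- (idx - 1) * ntrace$frame_interval_s
  pracma::trapz(t, v[idx])
}
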
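#' FRAP trace container
#'
#' The first `n_prebleach` frames are prebleach; the bleach happens between
#' frames `n_prebleach` and `n_prebleach + 1`, and the post-bleach clock
#' starts at the first post-bleach frame (t = 0).
#'
#' @param values Intensity per frame.
#' @param frame_interval_s Frame interval (s); 8.5 s in the emulated
#'   mCherry-ER3 protocol.
#' @param n_prebleach Number of prebleach frames (default 10).
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(values, frame_interval_s = 8.5, n_prebleach = 10) {
  stopifnot(is.numeric(values), frame_interval_s > 0, n_prebleach >= 2)
  if (length(values) <= n_prebleach) {
    stop("trace must extend beyond the prebleach frames")
  }
  structure(
    list(values = as.numeric(values), frame_interval_s = frame_interval_s,
         n_prebleach = as.integer(n_prebleach)),
    class = "frap_trace"
  )
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf(
    "<frap_trace: %d prebleach + %d post-bleach frames, dt = %g s>\n",
    x$n_prebleach, length(x$values) - x$n_prebleach, x$frame_interval_s
  ))
  invisible(x)
}

#' Normalize a FRAP trace to its prebleach baseline
#'
#' F0 is the mean of the prebleach frames; all frames are divided by it, so
#' the prebleach mean maps to 1. No rescaling to the bleach floor is applied
#' by default (`full_scale = TRUE` rescales to
#' `(F - F_post)/(F0 - F_post)` using the first post-bleach frame as floor);
#' under a complete bleach the two conventions coincide.
#'
#' @param trace A [frap_trace()].
#' @param full_scale Rescale to the bleach floor (default FALSE).
#' @return An object of class `frap_normalized` with `values`,
#'   `time_post_s` (post-bleach clock; NA for prebleach frames), `f0`.
#' @export
normalize_frap <- function(trace, full_scale = FALSE) {
  stopifnot(inherits(trace, "frap_trace"))
  pre <- trace$values[seq_len(trace$n_prebleach)]
  f0 <- mean(pre)
  if (f0 <= 0) stop("prebleach F0 <= 0")
  v <- trace$values / f0
  n_post <- length(trace$values) - trace$n_prebleach
  if (full_scale) {
    floor_val <- v[trace$n_prebleach + 1]
    if (floor_val >= 1) stop("no bleach detected; cannot rescale to floor")
    v <- (v - floor_val) / (1 - floor_val)
  }
  structure(
    list(
      values = v,
      time_post_s = c(rep(NA_real_, trace$n_prebleach),
                      (seq_len(n_post) - 1) * trace$frame_interval_s),
      f0 = f0,
      frame_interval_s = trace$frame_interval_s,
      n_prebleach = trace$n_prebleach,
      full_scale = full_scale
    ),
    class = "frap_normalized"
  )
}

#' Normalized recovery at a time after photobleaching
#'
#' Linear interpolation between post-bleach frames.
#'
#' @param normalized A [normalize_frap()] result.
#' @param t_s Time after the bleach (s), within the recording.
#' @return Normalized fluorescence at `t_s`.
#' @export
recovery_at <- function(normalized, t_s) {
  stopifnot(inherits(normalized, "frap_normalized"))
  post <- !is.na(normalized$time_post_s)
  t <- normalized$time_post_s[post]
  v <- normalized$values[post]
  if (t_s < min(t) || t_s > max(t)) {
    stop(sprintf("t = %g s is outside the post-bleach recording [%g, %g] s",
                 t_s, min(t), max(t)))
  }
  stats::approx(t, v, xout = t_s)$y
}

#' Fit an exponential recovery to a normalized FRAP trace
#'
#' Least-squares fit of `floor + mobile * (1 - exp(-t/tau))` over the
#' post-bleach frames.
#'
#' @param normalized A [normalize_frap()] result with >= 8 post-bleach
#'   frames.
#' @return List with `mobile_fraction`, `tau_s`, `floor`, `converged`; the
#'   estimates are NA when the fit does not converge.
#' @export
fit_recovery <- function(normalized) {
  stopifnot(inherits(normalized, "frap_normalized"))
  post <- !is.na(normalized$time_post_s)
  t <- normalized$time_post_s[post]
  v <- normalized$values[post]
  if (length(t) < 8) stop("need at least 8 post-bleach samples")
  if (diff(range(v)) < 1e-8 * max(1, abs(mean(v)))) {
    # no recovery at all: the mobile fraction is zero and tau is undefined
    return(list(mobile_fraction = 0, tau_s = NA_real_,
                floor = mean(v), converged = TRUE))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ fl + mobile * (1 - exp(-t / tau)),
      start = list(fl = v[1], mobile = max(max(v) - v[1], 0.05),
                   tau = max(diff(range(t)) / 5, 1)),
      lower = c(fl = -0.5, mobile = 0, tau = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(mobile_fraction = NA_real_, tau_s = NA_real_,
                floor = NA_real_, converged = FALSE))
  }
  cf <- stats::coef(fit)
  list(mobile_fraction = unname(cf["mobile"]), tau_s = unname(cf["tau"]),
       floor = unname(cf["fl"]), converged = TRUE)
}
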
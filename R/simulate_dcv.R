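#' Parameters for the DCV fusion-movie simulator
#'
#' Defaults emulate the regime of the NPY-pHluorin single-vesicle assays:
#' a 60-vesicle intracellular pool, on average 12 fusion events per cell
#' during a 16-burst train, events of peak-pixel amplitude 0.5 * baseline
#' (so peak SNR = 8 at the default noise), a 1 px point-spread sigma at
#' 200 nm pixels, and 2 Hz sampling.
#'
#' @param pool_size Number of vesicles in the cell.
#' @param mean_events_per_cell Poisson mean of fusion events during the
#'   protocol (truncated at `pool_size`; at most one fusion per vesicle).
#' @param event_rate_multiplier Thinning factor in (0, 1] applied to the
#'   base event draw; with a shared seed this couples a manipulated
#'   condition to its control (common random numbers), while the marginal
#'   event count stays exactly Poisson(mean * multiplier).
#' @param event_amplitude Peak-pixel amplitude of one fusion event, as a
#'   fraction of `baseline_level` (dFF units at the brightest pixel).
#' @param event_rise_s,event_decay_s Rise and decay time constants (s) of
#'   the event intensity profile. The rise starts at the first frame at or
#'   after the event onset (frame-integrated appearance).
#' @param psf_sigma_px Gaussian point-spread sigma (px).
#' @param baseline_level Baseline intensity (camera counts).
#' @param noise_sd Additive Gaussian noise SD per pixel (counts); the
#'   default gives per-event peak SNR (peak - baseline)/noise_sd = 8.
#' @param frame_interval_s Frame interval (s); default 0.5 (2 Hz).
#' @param field_shape `(ny, nx)` field size in pixels.
#' @param duration_s Movie duration (s).
#' @param nh4cl_amplitude Peak-pixel amplitude of the NH4Cl dequenching
#'   plateau per vesicle; defaults to `event_amplitude`.
#' @param noise_model `"gaussian"` (additive, EM-CCD regime proxy) or
#'   `"poisson"` (shot noise on the expected counts).
#' @param margin_px Border margin inside which no vesicle is placed.
#' @param min_separation_px Minimum Euclidean separation between vesicles.
#'   The default 4 px is the resolvability limit of the detection chain: two
#'   unit-amplitude puncta with a 1 px PSF sigma merge into a single peak
#'   after the 1 px detection smoothing when closer than about 3.5 px.
#' @param seed Integer seed; identical seed and parameters give a
#'   bit-identical movie.
#' @return An object of class `dcv_sim_params`.
#' @export
dcv_sim_params <- function(pool_size = 60,
                           mean_events_per_cell = 12,
                           event_rate_multiplier = 1,
                           event_amplitude = 0.5,
                           event_rise_s = 0.5,
                           event_decay_s = 3,
                           psf_sigma_px = 1,
                           baseline_level = 100,
                           noise_sd = 6.25,
                           frame_interval_s = 0.5,
                           field_shape = c(64, 64),
                           duration_s = 60,
                           nh4cl_amplitude = NULL,
                           noise_model = c("gaussian", "poisson"),
                           margin_px = 4,
                           min_separation_px = 4,
                           seed = 1) {
  noise_model <- match.arg(noise_model)
  stopifnot(
    pool_size >= 0, mean_events_per_cell >= 0,
    mean_events_per_cell <= pool_size,
    event_rate_multiplier > 0, event_rate_multiplier <= 1,
    event_amplitude >= 0, event_rise_s >= 0, event_decay_s > 0,
    psf_sigma_px > 0, baseline_level > 0, noise_sd >= 0,
    frame_interval_s > 0, length(field_shape) == 2, all(field_shape >= 8),
    duration_s > 0
  )
  if (is.null(nh4cl_amplitude)) nh4cl_amplitude <- event_amplitude
  structure(
    list(
      pool_size = as.integer(pool_size),
      mean_events_per_cell = mean_events_per_cell,
      event_rate_multiplier = event_rate_multiplier,
      event_amplitude = event_amplitude,
      event_rise_s = event_rise_s,
      event_decay_s = event_decay_s,
      psf_sigma_px = psf_sigma_px,
      baseline_level = baseline_level,
      noise_sd = noise_sd,
      frame_interval_s = frame_interval_s,
      field_shape = as.integer(field_shape),
      duration_s = duration_s,
      nh4cl_amplitude = nh4cl_amplitude,
      noise_model = noise_model,
      margin_px = as.integer(margin_px),
      min_separation_px = min_separation_px,
      seed = as.integer(seed)
    ),
    class = "dcv_sim_params"
  )
}

#' Simulate an NPY-pHluorin DCV fusion movie with ground truth
#'
#' Vesicles are placed uniformly (integer pixels, minimum separation) inside
#' the field margin. A Poisson number of them fuse during the stimulation
#' train: each fusion renders as a Gaussian punctum whose peak-pixel trace
#' rises over `event_rise_s` from the first frame at or after its onset and
#' then decays exponentially. During the NH4Cl window every pool vesicle is
#' dequenched to plateau brightness (2 s wash-in ramp). Event onsets are
#' burst-locked: uniform within a uniformly chosen burst.
#'
#' @param params A [dcv_sim_params()].
#' @param protocol A [stimulation_protocol()]; default the 16x50AP@50Hz train.
#' @param perfusion A [perfusion_schedule()] whose NH4Cl window follows the
#'   stimulation epoch.
#' @return A list with `movie` (a [time_lapse_movie()]) and `truth` (class
#'   `ground_truth`: `events` data.frame with 0-based `y`, `x`, `onset_s`,
#'   `amplitude_dff`, `rise_s`; `pool` positions; `pool_size`).
#' @export
simulate_dcv_movie <- function(params,
                               protocol = protocol_preset("DCV_TRAIN"),
                               perfusion = perfusion_schedule(nh4cl_window = c(45, 60))) {
  stopifnot(inherits(params, "dcv_sim_params"))
  if (is.null(perfusion$nh4cl_window)) stop("perfusion must include an NH4Cl window")
  span <- stimulation_span(protocol)
  if (perfusion$nh4cl_window[1] < span[2]) {
    stop("NH4Cl window must follow the stimulation epoch")
  }
  if (length(protocol$burst_onsets) == 0) stop("empty stimulation protocol")

  ny <- params$field_shape[1]; nx <- params$field_shape[2]
  dt <- params$frame_interval_s
  nf <- ceiling(params$duration_s / dt)
  times <- (seq_len(nf) - 1) * dt

  seeds <- derive_seeds(params$seed, 3)

  # -- vesicle placement (stream 1)
  set.seed(seeds[1])
  pos <- place_vesicles(params$pool_size, ny, nx, params$margin_px,
                        params$min_separation_px)

  # -- event draw (stream 2); all base draws happen before thinning so that
  #    the same seed yields a coupled subset under a smaller multiplier
  set.seed(seeds[2])
  n_base <- min(stats::rpois(1, params$mean_events_per_cell), params$pool_size)
  ves_idx <- if (n_base > 0) sample(params$pool_size, n_base) else integer(0)
  burst_idx <- if (n_base > 0) {
    sample(length(protocol$burst_onsets), n_base, replace = TRUE)
  } else integer(0)
  u_onset <- stats::runif(max(n_base, 1)) # drawn even when unused, for stream stability
  u_thin <- stats::runif(max(n_base, 1))
  keep <- if (n_base > 0) u_thin[seq_len(n_base)] < params$event_rate_multiplier else logical(0)

  events <- data.frame(
    vesicle = ves_idx[keep],
    y = pos[ves_idx[keep], 1],
    x = pos[ves_idx[keep], 2],
    onset_s = protocol$burst_onsets[burst_idx[keep]] +
      u_onset[seq_len(n_base)][keep] * burst_duration(protocol),
    amplitude_dff = rep(params$event_amplitude, sum(keep)),
    rise_s = rep(params$event_rise_s, sum(keep))
  )
  if (nrow(events) > 0) events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL

  # -- rendering (no RNG)
  frames <- array(params$baseline_level, dim = c(nf, ny, nx))
  psf <- params$psf_sigma_px
  amp_px <- params$event_amplitude * params$baseline_level
  rise_frames <- max(1L, ceiling(params$event_rise_s / dt))
  for (k in seq_len(nrow(events))) {
    k0 <- which(times >= events$onset_s[k])[1]
    if (is.na(k0)) next
    el <- (seq(k0, nf) - k0 + 1) * dt            # elapsed since appearance
    rise_eff <- max(params$event_rise_s, dt)
    a <- amp_px * pmin(1, el / rise_eff)
    post <- el > rise_eff
    a[post] <- amp_px * exp(-(el[post] - rise_eff) / params$event_decay_s)
    frames <- add_punctum(frames, events$y[k], events$x[k], psf, seq(k0, nf), a)
  }

  # -- NH4Cl dequenching of the whole pool
  w <- perfusion$nh4cl_window
  nh_idx <- which(times >= w[1] & times < w[2])
  if (length(nh_idx) > 0 && params$pool_size > 0) {
    template <- matrix(0, ny, nx)
    for (v in seq_len(params$pool_size)) {
      template <- template +
        punctum_patch_into(matrix(0, ny, nx), pos[v, 1], pos[v, 2], psf)
    }
    ramp <- pmin(1, (times[nh_idx] - w[1]) / 2) # 2 s wash-in
    amp_n <- params$nh4cl_amplitude * params$baseline_level
    for (j in seq_along(nh_idx)) {
      frames[nh_idx[j], , ] <- frames[nh_idx[j], , ] + amp_n * ramp[j] * template
    }
  }

  # -- noise (stream 3)
  set.seed(seeds[3])
  if (params$noise_model == "gaussian") {
    if (params$noise_sd > 0) {
      frames <- frames + array(stats::rnorm(length(frames), 0, params$noise_sd),
                               dim = dim(frames))
    }
  } else {
    frames <- array(stats::rpois(length(frames), pmax(frames, 0)),
                    dim = dim(frames))
  }
  frames[frames < 0] <- 0

  movie <- time_lapse_movie(frames, dt, 200, protocol = protocol,
                            perfusion = perfusion)
  truth <- structure(
    list(
      events = events,
      pool = data.frame(y = pos[, 1], x = pos[, 2]),
      pool_size = params$pool_size,
      true_tau_s = NULL,
      true_mobile_fraction = NULL,
      true_concentration_uM = NULL
    ),
    class = "ground_truth"
  )
  list(movie = movie, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth:",
      if (!is.null(x$events)) sprintf("%d events,", nrow(x$events)) else "",
      if (!is.null(x$pool_size)) sprintf("pool %d", x$pool_size) else "",
      ">\n")
  invisible(x)
}

# Uniform integer positions with a minimum separation, by rejection.
#' @keywords internal
place_vesicles <- function(n, ny, nx, margin, min_sep) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  ys <- numeric(0); xs <- numeric(0)
  lo_y <- margin; hi_y <- ny - 1 - margin   # 0-based bounds
  lo_x <- margin; hi_x <- nx - 1 - margin
  if (hi_y < lo_y || hi_x < lo_x) stop("field too small for the margin")
  attempts <- 0L
  max_attempts <- 2000L * n
  while (length(ys) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(
        "could not place %d vesicles with min separation %g in a %dx%d field",
        n, min_sep, ny, nx
      ))
    }
    y <- sample(lo_y:hi_y, 1)
    x <- sample(lo_x:hi_x, 1)
    if (length(ys) == 0 || all((ys - y)^2 + (xs - x)^2 >= min_sep^2)) {
      ys <- c(ys, y); xs <- c(xs, x)
    }
  }
  cbind(ys, xs)
}

# Add a Gaussian punctum (unit peak scaled by per-frame amplitudes) to a
# stack of frames at 0-based centre (y0, x0).
#' @keywords internal
add_punctum <- function(frames, y0, x0, sigma, frame_idx, amplitudes) {
  d <- dim(frames)
  r <- ceiling(3 * sigma) + 1
  rows <- max(1, y0 + 1 - r):min(d[2], y0 + 1 + r)
  cols <- max(1, x0 + 1 - r):min(d[3], x0 + 1 + r)
  g <- outer(rows - (y0 + 1), cols - (x0 + 1),
             function(dy, dx) exp(-(dy^2 + dx^2) / (2 * sigma^2)))
  for (j in seq_along(frame_idx)) {
    frames[frame_idx[j], rows, cols] <-
      frames[frame_idx[j], rows, cols] + amplitudes[j] * g
  }
  frames
}

#' @keywords internal
punctum_patch_into <- function(img, y0, x0, sigma) {
  r <- ceiling(3 * sigma) + 1
  rows <- max(1, y0 + 1 - r):min(nrow(img), y0 + 1 + r)
  cols <- max(1, x0 + 1 - r):min(ncol(img), x0 + 1 + r)
  g <- outer(rows - (y0 + 1), cols - (x0 + 1),
             function(dy, dx) exp(-(dy^2 + dx^2) / (2 * sigma^2)))
  img[rows, cols] <- img[rows, cols] + g
  img
}
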
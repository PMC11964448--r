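#' Detect fluorescent puncta in a single image
#'
#' The image is Gaussian-smoothed (sigma 1 px, matching the rendered point-
#' spread function scale) and flattened against a robust local background
#' (median filter of radius `local_bg_radius`, so crowded fields do not
#' inflate the threshold); the noise level is the 1.4826*MAD of the
#' flattened image, and puncta are its local maxima exceeding
#' `median + threshold_k * noise`, thinned so that no two detections lie
#' closer than `min_separation_px` (greedy suppression in order of
#' descending intensity, ties broken row-major). Median/MAD are used instead
#' of mean/SD so that bright puncta themselves do not set the threshold.
#'
#' @param image 2-D numeric intensity matrix.
#' @param min_separation_px Minimum centre separation (px); detections closer
#'   than this are merged into the brighter one.
#' @param threshold_k Threshold in robust-noise units above the robust
#'   background.
#' @param smooth_sigma Gaussian smoothing sigma (px).
#' @param local_bg_radius Radius (px) of the median-filter background; the
#'   default 4 px window comfortably spans one smoothed punctum.
#' @return A data.frame with 0-based columns `y`, `x` and the
#'   background-subtracted smoothed `intensity`, ordered by descending
#'   intensity.
#' @export
detect_puncta <- function(image, min_separation_px = 3, threshold_k = 4,
                          smooth_sigma = 1, local_bg_radius = 4) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  sm <- gaussian_smooth(image, smooth_sigma)
  sm <- sm - local_median_background(sm, local_bg_radius)
  bg <- stats::median(sm)
  noise <- stats::mad(sm)   # 1.4826 * MAD
  thr <- bg + threshold_k * max(noise, 1e-12)
  peaks <- local_maxima(sm, thr)
  if (nrow(peaks) == 0) {
    return(data.frame(y = integer(0), x = integer(0), intensity = numeric(0)))
  }
  keep <- nms(peaks, min_separation_px)
  out <- peaks[keep, , drop = FALSE]
  data.frame(y = out[, "y"] - 1L, x = out[, "x"] - 1L,
             intensity = out[, "intensity"], row.names = NULL)
}

# Separable Gaussian smoothing; sigma 0 returns the image unchanged.
#' @keywords internal
gaussian_smooth <- function(image, sigma) {
  if (sigma <= 0) return(image)
  EBImage::gblur(image, sigma = sigma)
}

# Robust local background: median filter on the range-normalized image.
# A flat image is its own background.
#' @keywords internal
local_median_background <- function(image, radius) {
  rng <- range(image)
  if (radius <= 0 || diff(rng) == 0) return(image * 0 + rng[1])
  scaled <- (image - rng[1]) / diff(rng)
  EBImage::medianFilter(scaled, radius) * diff(rng) + rng[1]
}

# All strict-or-tied 8-neighbourhood local maxima above thr, as a matrix with
# 1-based y, x and intensity, ordered by descending intensity then row-major.
#' @keywords internal
local_maxima <- function(sm, thr) {
  ny <- nrow(sm); nx <- ncol(sm)
  if (ny < 3 || nx < 3) return(matrix(numeric(0), 0, 3,
                                      dimnames = list(NULL, c("y", "x", "intensity"))))
  core <- sm[2:(ny - 1), 2:(nx - 1)]
  is_max <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- sm[(2 + dy):(ny - 1 + dy), (2 + dx):(nx - 1 + dx)]
    is_max <- is_max & (core >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(0), 0, 3,
                                    dimnames = list(NULL, c("y", "x", "intensity"))))
  ys <- idx[, 1] + 1L
  xs <- idx[, 2] + 1L
  ints <- sm[cbind(ys, xs)]
  ord <- order(-ints, ys, xs)
  cbind(y = ys[ord], x = xs[ord], intensity = ints[ord])
}

# Greedy non-maximum suppression: walk peaks in their (already sorted)
# order, keep a peak only if all kept peaks are >= min_sep away.
#' @keywords internal
nms <- function(peaks, min_sep) {
  n <- nrow(peaks)
  keep <- logical(n)
  ky <- numeric(0); kx <- numeric(0)
  for (i in seq_len(n)) {
    if (length(ky) == 0 ||
        all((ky - peaks[i, "y"])^2 + (kx - peaks[i, "x"])^2 >= min_sep^2)) {
      keep[i] <- TRUE
      ky <- c(ky, peaks[i, "y"])
      kx <- c(kx, peaks[i, "x"])
    }
  }
  keep
}

#' Count the total vesicle pool from the NH4Cl dequenching plateau
#'
#' NH4Cl alkalinises all vesicle lumens, so every pHluorin-labelled vesicle
#' lights up; the pool is the number of puncta in the mean projection over
#' the NH4Cl plateau. The plateau is taken as the last 50% of the NH4Cl
#' window, skipping the wash-in ramp.
#'
#' @param movie A [time_lapse_movie()].
#' @param perfusion A [perfusion_schedule()] with an NH4Cl window; defaults
#'   to the movie's own schedule.
#' @param ... Passed to [detect_puncta()].
#' @return Integer pool count, with the detected centres attached as
#'   attribute `"centers"`.
#' @export
count_pool_nh4cl <- function(movie, perfusion = movie$perfusion, ...) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  if (is.null(perfusion) || is.null(perfusion$nh4cl_window)) {
    stop("no NH4Cl window in the perfusion schedule")
  }
  w <- perfusion$nh4cl_window
  all_idx <- frames_in_window(n_frames(movie), movie$frame_interval_s, w)
  if (length(all_idx) < 3) {
    stop("NH4Cl window covers fewer than 3 frames")
  }
  plateau <- nh4cl_plateau_frames(n_frames(movie), movie$frame_interval_s, w)
  proj <- apply(movie$frames[plateau, , , drop = FALSE], c(2, 3), mean)
  centers <- detect_puncta(proj, ...)
  structure(nrow(centers), centers = centers)
}

# Frame indices of the NH4Cl plateau (last 50% of the window).
#' @keywords internal
nh4cl_plateau_frames <- function(n, dt, window) {
  half <- c(window[1] + diff(window) / 2, window[2])
  idx <- frames_in_window(n, dt, half)
  if (length(idx) == 0) idx <- frames_in_window(n, dt, window)
  idx
}
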
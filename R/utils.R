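# Internal helpers shared across modules.

# Frame index <-> time convention: frame i (1-based in R) sits at
# t = (i - 1) * frame_interval_s, i.e. frame 0 at t = 0 in the 0-based
# convention used in all user-facing coordinates.

#' @keywords internal
frames_in_window <- function(n_frames, frame_interval_s, window,
                             closed = FALSE) {
  t <- (seq_len(n_frames) - 1) * frame_interval_s
  if (closed) {
    which(t >= window[1] & t <= window[2])
  } else {
    which(t >= window[1] & t < window[2])
  }
}

#' @keywords internal
frame_times <- function(n_frames, frame_interval_s) {
  (seq_len(n_frames) - 1) * frame_interval_s
}

#' @keywords internal
check_window <- function(window, what = "window") {
  if (!is.numeric(window) || length(window) != 2 || any(!is.finite(window)) ||
      window[2] <= window[1]) {
    stop(sprintf("'%s' must be a finite interval c(start, end) with end > start", what))
  }
  invisible(window)
}

# Pairwise Euclidean distances between (y, x) rows of two matrices.
#' @keywords internal
cross_dist <- function(a, b) {
  dy <- outer(a[, 1], b[, 1], "-")
  dx <- outer(a[, 2], b[, 2], "-")
  sqrt(dy^2 + dx^2)
}

#' Derive reproducible sub-stream seeds from one top-level seed
#'
#' All simulators split their top-level seed into independent stream seeds
#' (placement, event timing, noise, ...) through this map, so that one
#' integer reproduces an entire simulated experiment.
#'
#' @param seed Integer top-level seed.
#' @param n Number of stream seeds to derive.
#' @return Integer vector of length `n`, each usable with [set.seed()].
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
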
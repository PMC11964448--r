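#' Time-lapse fluorescence movie
#'
#' A single-channel movie stored as a 3-D array indexed `[frame, y, x]`,
#' together with its acquisition metadata. All pixel coordinates exposed by
#' this package are 0-based `(y, x)` pairs; frame `i` (0-based) sits at time
#' `i * frame_interval_s`.
#'
#' @param frames 3-D numeric array `(time, y, x)` of non-negative intensities.
#' @param frame_interval_s Frame interval (s).
#' @param pixel_size_nm Pixel size (nm); 200 nm for the EM-CCD setup emulated
#'   by the simulator.
#' @param protocol Optional [stimulation_protocol()].
#' @param perfusion Optional [perfusion_schedule()].
#' @return An object of class `time_lapse_movie`.
#' @export
time_lapse_movie <- function(frames, frame_interval_s, pixel_size_nm = 200,
                             protocol = NULL, perfusion = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3) {
    stop("frames must be a 3-D array (time, y, x)")
  }
  if (any(frames < 0)) stop("movie intensities must be non-negative")
  stopifnot(frame_interval_s > 0, pixel_size_nm > 0)
  structure(
    list(
      frames = frames,
      frame_interval_s = frame_interval_s,
      pixel_size_nm = pixel_size_nm,
      protocol = protocol,
      perfusion = perfusion
    ),
    class = "time_lapse_movie"
  )
}

#' @export
print.time_lapse_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<time_lapse_movie: %d frames of %dx%d px, dt = %g s (%.3g s total), %g nm/px>\n",
    d[1], d[2], d[3], x$frame_interval_s, d[1] * x$frame_interval_s,
    x$pixel_size_nm
  ))
  if (!is.null(x$protocol)) print(x$protocol)
  if (!is.null(x$perfusion)) print(x$perfusion)
  invisible(x)
}

#' @export
dim.time_lapse_movie <- function(x) dim(x$frames)

#' Number of frames in a movie
#' @param movie A [time_lapse_movie()].
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[1]

#' Extract a single frame as a matrix
#' @param movie A [time_lapse_movie()].
#' @param i Frame index (1-based R index).
#' @return A `y x x` intensity matrix.
#' @export
movie_frame <- function(movie, i) {
  movie$frames[i, , ]
}

# ---- External interface: multi-page TIFF + YAML sidecar ----------------

#' Write a movie as a 16-bit multi-page TIFF with a YAML metadata sidecar
#'
#' Intensities are rounded to integers and stored as 16-bit samples; the
#' sidecar (same path with extension `.yaml`) records the frame interval,
#' pixel size and any stimulation/perfusion schedule so that
#' [read_movie_tiff()] restores a fully annotated movie.
#'
#' @param movie A [time_lapse_movie()]. Intensities must fit in 0..65535.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  mx <- max(movie$frames)
  if (mx > 65535) stop("intensities exceed the 16-bit range")
  pages <- lapply(seq_len(n_frames(movie)), function(i) {
    round(movie$frames[i, , ]) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(
    frame_interval_s = movie$frame_interval_s,
    pixel_size_nm = movie$pixel_size_nm
  )
  if (!is.null(movie$protocol)) {
    meta$protocol <- list(
      burst_onsets = movie$protocol$burst_onsets,
      pulses_per_burst = movie$protocol$pulses_per_burst,
      pulse_rate_hz = movie$protocol$pulse_rate_hz,
      label = movie$protocol$label
    )
  }
  if (!is.null(movie$perfusion)) {
    meta$perfusion <- list(
      nh4cl_window = movie$perfusion$nh4cl_window,
      ionomycin_onset = movie$perfusion$ionomycin_onset,
      caffeine_window = movie$perfusion$caffeine_window
    )
  }
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF path; the YAML sidecar is looked up next to it unless
#'   `meta_path` is given.
#' @param meta_path Optional explicit sidecar path.
#' @return A [time_lapse_movie()].
#' @export
read_movie_tiff <- function(path, meta_path = sidecar_path(path)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  frames <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) frames[i, , ] <- round(pages[[i]] * 65535)
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  protocol <- NULL
  if (!is.null(meta$protocol)) {
    protocol <- stimulation_protocol(
      meta$protocol$burst_onsets, meta$protocol$pulses_per_burst,
      meta$protocol$pulse_rate_hz, meta$protocol$label
    )
  }
  perfusion <- NULL
  if (!is.null(meta$perfusion)) {
    perfusion <- perfusion_schedule(
      nh4cl_window = unlist(meta$perfusion$nh4cl_window),
      ionomycin_onset = meta$perfusion$ionomycin_onset,
      caffeine_window = unlist(meta$perfusion$caffeine_window)
    )
  }
  time_lapse_movie(frames, meta$frame_interval_s, meta$pixel_size_nm,
                   protocol = protocol, perfusion = perfusion)
}

#' @keywords internal
sidecar_path <- function(path) {
  sub("\\.tiff?$", ".yaml", path, ignore.case = TRUE)
}
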
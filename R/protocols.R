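#' Electrical field-stimulation protocol
#'
#' Describes a train of action-potential bursts: when each burst starts, how
#' many pulses it contains and at what rate. Burst duration is
#' `pulses_per_burst / pulse_rate_hz` seconds.
#'
#' @param burst_onsets Strictly increasing burst start times (s), all >= 0.
#' @param pulses_per_burst Number of field pulses per burst.
#' @param pulse_rate_hz Pulse rate within a burst (Hz).
#' @param label Free-text protocol name.
#' @return An object of class `stimulation_protocol`.
#' @seealso [protocol_preset()]
#' @export
stimulation_protocol <- function(burst_onsets, pulses_per_burst, pulse_rate_hz,
                                 label = "custom") {
  if (length(burst_onsets) < 1 || any(!is.finite(burst_onsets)) ||
      any(burst_onsets < 0)) {
    stop("burst_onsets must be non-negative finite times")
  }
  if (is.unsorted(burst_onsets, strictly = TRUE)) {
    stop("burst_onsets must be strictly increasing")
  }
  stopifnot(pulses_per_burst >= 1, pulse_rate_hz > 0)
  structure(
    list(
      burst_onsets = as.numeric(burst_onsets),
      pulses_per_burst = as.integer(pulses_per_burst),
      pulse_rate_hz = as.numeric(pulse_rate_hz),
      label = label
    ),
    class = "stimulation_protocol"
  )
}

#' @export
print.stimulation_protocol <- function(x, ...) {
  cat(sprintf(
    "<stimulation_protocol '%s': %d burst(s) of %d pulses at %g Hz, t0 = %g s>\n",
    x$label, length(x$burst_onsets), x$pulses_per_burst, x$pulse_rate_hz,
    x$burst_onsets[1]
  ))
  invisible(x)
}

#' Duration of a single burst (s)
#' @param protocol A [stimulation_protocol()].
#' @return Burst duration in seconds.
#' @export
burst_duration <- function(protocol) {
  protocol$pulses_per_burst / protocol$pulse_rate_hz
}

#' Stimulation epoch (first burst onset to end of last burst)
#' @param protocol A [stimulation_protocol()].
#' @return `c(start, end)` in seconds.
#' @export
stimulation_span <- function(protocol) {
  c(protocol$burst_onsets[1],
    protocol$burst_onsets[length(protocol$burst_onsets)] + burst_duration(protocol))
}

#' Stimulation protocol presets
#'
#' The three protocols used throughout: `"DCV_TRAIN"`, 16 bursts of 50 APs at
#' 50 Hz (dense-core-vesicle fusion assays); `"SV_HFS"`, one 5 s epoch at
#' 40 Hz (SypHy synaptic-vesicle assays); `"CA_BURST"`, a single burst of 16
#' APs at 50 Hz (cytosolic Ca2+ responses).
#'
#' @param name One of `"DCV_TRAIN"`, `"SV_HFS"`, `"CA_BURST"`.
#' @param onset_s Start of the first burst (s). Default 10 leaves a 10 s
#'   baseline for F0 estimation.
#' @param burst_spacing_s Onset-to-onset spacing for multi-burst trains (s).
#' @return A [stimulation_protocol()].
#' @export
protocol_preset <- function(name = c("DCV_TRAIN", "SV_HFS", "CA_BURST"),
                            onset_s = 10, burst_spacing_s = 2) {
  name <- match.arg(name)
  switch(name,
    DCV_TRAIN = stimulation_protocol(onset_s + burst_spacing_s * (0:15),
                                     50, 50, label = "DCV_TRAIN"),
    SV_HFS = stimulation_protocol(onset_s, 200, 40, label = "SV_HFS"),
    CA_BURST = stimulation_protocol(onset_s, 16, 50, label = "CA_BURST")
  )
}

#' Perfusion schedule
#'
#' Records when bath solutions were exchanged: the NH4Cl dequenching window
#' (reveals the total pHluorin-labelled vesicle pool), an ionomycin
#' application (saturates ER-GCaMP indicators) and a caffeine window
#' (depletes ER Ca2+ through ryanodine receptors). Windows are half-open
#' `[start, end)` and must not overlap.
#'
#' @param nh4cl_window,caffeine_window Length-2 interval in seconds, or NULL.
#' @param ionomycin_onset Onset time (s), or NULL.
#' @return An object of class `perfusion_schedule`.
#' @export
perfusion_schedule <- function(nh4cl_window = NULL, ionomycin_onset = NULL,
                               caffeine_window = NULL) {
  if (!is.null(nh4cl_window)) check_window(nh4cl_window, "nh4cl_window")
  if (!is.null(caffeine_window)) check_window(caffeine_window, "caffeine_window")
  if (!is.null(nh4cl_window) && !is.null(caffeine_window)) {
    if (nh4cl_window[1] < caffeine_window[2] &&
        caffeine_window[1] < nh4cl_window[2]) {
      stop("nh4cl_window and caffeine_window overlap")
    }
  }
  if (!is.null(ionomycin_onset)) {
    stopifnot(is.finite(ionomycin_onset), ionomycin_onset >= 0)
  }
  structure(
    list(
      nh4cl_window = nh4cl_window,
      ionomycin_onset = ionomycin_onset,
      caffeine_window = caffeine_window
    ),
    class = "perfusion_schedule"
  )
}

#' @export
print.perfusion_schedule <- function(x, ...) {
  fmt <- function(w) if (is.null(w)) "none" else sprintf("[%g, %g) s", w[1], w[2])
  cat("<perfusion_schedule>\n")
  cat("  NH4Cl:     ", fmt(x$nh4cl_window), "\n")
  cat("  ionomycin: ",
      if (is.null(x$ionomycin_onset)) "none" else sprintf("onset %g s", x$ionomycin_onset), "\n")
  cat("  caffeine:  ", fmt(x$caffeine_window), "\n")
  invisible(x)
}
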
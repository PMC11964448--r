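# Shared fixtures: tiny movies and traces built in code.

# A constant movie with optional protocol/perfusion.
flat_movie <- function(level = 100, nf = 30, ny = 16, nx = 16, dt = 0.5,
                       protocol = NULL, perfusion = NULL) {
  time_lapse_movie(array(level, dim = c(nf, ny, nx)), dt,
                   protocol = protocol, perfusion = perfusion)
}

# A raw trace wrapped as roi_trace.
raw_trace <- function(values, dt = 0.5) roi_trace(values, dt)

# A dFF normalized_trace built directly from known f0/sd (bypasses the
# leading-baseline convention when a test needs full control).
make_ntrace <- function(dff, f0 = 100, baseline_sd = 2, dt = 0.5) {
  structure(
    list(values = dff, f0 = f0, baseline_sd = baseline_sd, mode = "dFF",
         frame_interval_s = dt, n_baseline = 10L),
    class = "normalized_trace"
  )
}

# Greedy one-to-one matching of detected (y, x) centres to truth centres.
match_centers <- function(detected, truth, tol = 2) {
  if (nrow(truth) == 0 || nrow(detected) == 0) return(0L)
  d <- sqrt(outer(detected$y, truth$y, "-")^2 + outer(detected$x, truth$x, "-")^2)
  matched <- 0L
  used_det <- rep(FALSE, nrow(detected))
  used_tru <- rep(FALSE, nrow(truth))
  repeat {
    d2 <- d
    d2[used_det, ] <- Inf
    d2[, used_tru] <- Inf
    if (all(!is.finite(d2)) || min(d2) > tol) break
    ij <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    used_det[ij[1]] <- TRUE
    used_tru[ij[2]] <- TRUE
    matched <- matched + 1L
  }
  matched
}
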
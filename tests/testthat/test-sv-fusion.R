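test_that("active-synapse classification applies the inclusive 3 SD criterion", {
  dt <- 0.5
  # baseline_sd/f0 = 0.01: threshold 0.03 in dFF
  mk <- function(peak) {
    v <- rep(0, 40); v[25] <- peak
    make_ntrace(v, f0 = 100, baseline_sd = 1, dt = dt)
  }
  w <- c(10, 15)
  expect_true(classify_active(mk(0.05), w))
  expect_true(classify_active(mk(0.03), w))    # inclusive boundary
  expect_false(classify_active(mk(0.029), w))
  expect_false(classify_active(mk(0), w))
  expect_error(classify_active(mk(0.05), c(100, 120)), "no frames")
})

test_that("raising the SD multiplier never activates an inactive synapse", {
  sim <- simulate_syphy_traces(n_synapses = 24, active_fraction = 0.5,
                               noise_sd = 3, seed = 5)
  span <- stimulation_span(sim$protocol)
  nts <- lapply(sim$traces, normalize_trace, n_baseline = 10, mode = "dFF")
  prev <- rep(TRUE, 24)
  for (k in c(1, 2, 3, 5, 8)) {
    act <- vapply(nts, classify_active, logical(1), stim_window = span,
                  sd_multiplier = k)
    expect_true(all(act | !prev | !act))      # act implies prev
    expect_true(all(!act | prev))
    prev <- act
  }
})

test_that("fused fraction is the stim/NH4Cl dFF ratio and gain-invariant", {
  sim <- simulate_syphy_traces(n_synapses = 4, active_fraction = 1,
                               stim_amplitude = 0.3, nh4cl_amplitude = 1,
                               noise_sd = 0, seed = 7)
  span <- stimulation_span(sim$protocol)
  w <- sim$perfusion$nh4cl_window
  nt <- normalize_trace(sim$traces[[1]], 10, "dFF")
  f <- sv_fused_fraction(nt, span, w)
  expect_equal(f, 0.3, tolerance = 2e-3)

  gained <- sim$traces[[1]]
  gained$values <- gained$values * 12.5
  expect_equal(sv_fused_fraction(normalize_trace(gained, 10, "dFF"), span, w),
               f, tolerance = 1e-12)

  # a silent synapse has fraction ~ 0; an NH4Cl-free trace errors
  silent <- sim$traces[[1]]
  silent$values <- rep(100, length(silent$values))
  expect_error(sv_fused_fraction(normalize_trace(silent, 10, "dFF"), span, w),
               "dequenching")
})

test_that("synapse ROIs are recovered from the NH4Cl difference image", {
  # a movie whose pool lights up only during NH4Cl is the synapse map
  sim <- simulate_dcv_movie(dcv_sim_params(pool_size = 40,
                                           mean_events_per_cell = 0,
                                           noise_sd = 0, seed = 9))
  rois <- identify_synapse_rois(sim$movie)
  expect_equal(length(rois), 40)
  det <- data.frame(
    y = vapply(rois, function(r) r$center[1], numeric(1)),
    x = vapply(rois, function(r) r$center[2], numeric(1))
  )
  expect_gte(match_centers(det, sim$truth$pool, tol = 1), 40L)

  # at SNR 8, at least 90% of synapses are recovered
  simN <- simulate_dcv_movie(dcv_sim_params(pool_size = 40,
                                            mean_events_per_cell = 0, seed = 9))
  roisN <- identify_synapse_rois(simN$movie)
  detN <- data.frame(
    y = vapply(roisN, function(r) r$center[1], numeric(1)),
    x = vapply(roisN, function(r) r$center[2], numeric(1))
  )
  expect_gte(match_centers(detN, simN$truth$pool, tol = 2), 36L)

  # empty field: no ROIs
  simE <- simulate_dcv_movie(dcv_sim_params(pool_size = 0,
                                            mean_events_per_cell = 0,
                                            noise_sd = 0, seed = 1))
  expect_equal(length(identify_synapse_rois(simE$movie)), 0)
})

test_that("endocytosis tau is recovered from noisy traces across seeds", {
  taus <- vapply(1:50, function(s) {
    sim <- simulate_syphy_traces(n_synapses = 1, active_fraction = 1,
                                 stim_amplitude = 0.3, tau_s = 15,
                                 noise_sd = 0.05 * 30, seed = s)
    nt <- normalize_trace(sim$traces[[1]], 10, "dFF")
    fit <- fit_endocytosis_tau(nt, post_stim_start = 15)
    fit$tau_s
  }, numeric(1))
  expect_lt(abs(median(taus, na.rm = TRUE) - 15), 1.5)
})

test_that("non-decaying traces fail the tau fit with a flag", {
  flat <- make_ntrace(rep(0, 200), dt = 0.5)
  fit <- fit_endocytosis_tau(flat, post_stim_start = 10)
  expect_false(fit$converged)
  expect_true(is.na(fit$tau_s))
})

test_that("active synapses pool into a rescaled per-neuron mean", {
  sim <- simulate_syphy_traces(n_synapses = 6, active_fraction = 1,
                               noise_sd = 0, seed = 3)
  span <- stimulation_span(sim$protocol)
  w <- sim$perfusion$nh4cl_window
  nts <- lapply(sim$traces, normalize_trace, n_baseline = 10, mode = "dFF")

  # identical traces: the mean equals each, NH4Cl max is 1 by construction
  pooled <- average_active_synapses(nts, rep(TRUE, 6), rep(0.3, 6), w)
  expect_equal(pooled$n_active, 6)
  expect_equal(pooled$mean_fused_fraction, 0.3)
  r1 <- as_dff(nts[[1]])
  idx <- which((seq_along(r1) - 1) * 0.5 >= w[1] & (seq_along(r1) - 1) * 0.5 < w[2])
  expect_equal(pooled$mean_trace, r1 / max(r1[idx]))
  expect_equal(max(pooled$mean_trace[idx]), 1)

  # mean of two different fractions
  pooled2 <- average_active_synapses(nts[1:2], c(TRUE, TRUE), c(0.2, 0.4), w)
  expect_equal(pooled2$mean_fused_fraction, 0.3)

  # zero active synapses: absent values, counted
  none <- average_active_synapses(nts, rep(FALSE, 6), rep(0.3, 6), w)
  expect_null(none$mean_trace)
  expect_true(is.na(none$mean_fused_fraction))
  expect_equal(none$n_active, 0L)
})

test_that("the full SypHy analysis recovers the programmed parameters", {
  sim <- simulate_syphy_traces(n_synapses = 30, active_fraction = 0.6,
                               stim_amplitude = 0.3, tau_s = 15,
                               noise_sd = 2, seed = 13)
  span <- stimulation_span(sim$protocol)
  res <- analyze_sv_traces(sim$traces, span, sim$perfusion$nh4cl_window)
  expect_equal(sum(res$records$active), sum(sim$truth$active))
  expect_equal(mean(res$records$fused_fraction[res$records$active]), 0.3,
               tolerance = 0.05)
  expect_equal(res$tau_s, 15, tolerance = 0.1 * 15)
})
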
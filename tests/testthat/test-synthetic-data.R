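test_that("simulators are bit-identical under a fixed seed", {
  p <- dcv_sim_params(seed = 3)
  a <- simulate_dcv_movie(p)
  b <- simulate_dcv_movie(p)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth$events, b$truth$events)

  s1 <- simulate_syphy_traces(seed = 4)
  s2 <- simulate_syphy_traces(seed = 4)
  expect_identical(lapply(s1$traces, `[[`, "values"),
                   lapply(s2$traces, `[[`, "values"))
})

test_that("event counts follow the programmed Poisson mean", {
  counts <- vapply(1:30, function(s) {
    nrow(simulate_dcv_movie(dcv_sim_params(noise_sd = 0, seed = s))$truth$events)
  }, numeric(1))
  se <- sqrt(12 / 30)
  expect_lt(abs(mean(counts) - 12), 3 * se)
})

test_that("rate thinning couples conditions and events stay burst-locked", {
  full <- simulate_dcv_movie(dcv_sim_params(noise_sd = 0, seed = 21))
  thin <- simulate_dcv_movie(dcv_sim_params(noise_sd = 0,
                                            event_rate_multiplier = 0.4,
                                            seed = 21))
  # thinned events are a subset of the full draw
  key <- function(e) paste(e$vesicle, signif(e$onset_s, 12))
  expect_true(all(key(thin$truth$events) %in% key(full$truth$events)))

  # all onsets inside the stimulation-to-NH4Cl interval, within a burst
  pr <- full$movie$protocol
  for (t0 in full$truth$events$onset_s) {
    expect_true(t0 >= pr$burst_onsets[1] &&
                t0 < full$movie$perfusion$nh4cl_window[1])
    expect_true(any(t0 >= pr$burst_onsets &
                    t0 <= pr$burst_onsets + burst_duration(pr)))
  }
})

test_that("programmed peak SNR follows from the generator parameters", {
  p <- dcv_sim_params(event_amplitude = 0.5, baseline_level = 100,
                      noise_sd = 6.25)
  peak_minus_baseline <- p$event_amplitude * p$baseline_level
  expect_equal(peak_minus_baseline / p$noise_sd, 8)
  # and the rendered movie honours it: brightest event pixel ~ baseline + 50
  sim <- simulate_dcv_movie(dcv_sim_params(noise_sd = 0, seed = 2))
  ev <- sim$truth$events
  k0 <- which((seq_len(n_frames(sim$movie)) - 1) * 0.5 >= ev$onset_s[1])[1]
  px <- sim$movie$frames[k0:(k0 + 1), ev$y[1] + 1, ev$x[1] + 1]
  expect_equal(max(px), 150, tolerance = 1e-6)
})

test_that("movie generation fails cleanly on impossible placements", {
  expect_error(
    simulate_dcv_movie(dcv_sim_params(pool_size = 60, field_shape = c(12, 12),
                                      mean_events_per_cell = 0)),
    "place"
  )
})

test_that("SypHy generator programs activity, ratio and decay exactly", {
  # all-active, noiseless: every trace exceeds the 3 SD criterion once a
  # noise floor is injected at analysis time
  sim <- simulate_syphy_traces(n_synapses = 10, active_fraction = 1,
                               noise_sd = 0, seed = 1)
  span <- stimulation_span(sim$protocol)
  for (tr in sim$traces) {
    nt <- normalize_trace(tr, 10, "dFF")
    nt$baseline_sd <- 0.01 * nt$f0   # injected noise floor
    expect_true(classify_active(nt, span))
  }

  # programmed fused fraction is amplitude ratio by construction
  expect_equal(sim$truth$fused_fraction, 0.3)
  nt <- normalize_trace(sim$traces[[1]], 10, "dFF")
  expect_equal(
    sv_fused_fraction(nt, span, sim$perfusion$nh4cl_window),
    0.3, tolerance = 2e-3
  )

  # noiseless decay recovers tau within 1%
  fit <- fit_endocytosis_tau(nt, post_stim_start = span[2])
  expect_true(fit$converged)
  expect_equal(fit$tau_s, 15, tolerance = 0.01)

  # active_fraction honoured exactly (rounded count)
  sim2 <- simulate_syphy_traces(n_synapses = 20, active_fraction = 0.25,
                                noise_sd = 0, seed = 2)
  expect_equal(sum(sim2$truth$active), 5)
})

test_that("ER-GCaMP forward model hits its analytic fixed points", {
  calib <- er_calibration()
  # zero calcium everywhere: trace sits at fmax/Rf
  z <- simulate_er_gcamp_trace(rep(0, 50), calib, fmax_level = 900)
  expect_equal(z$trace$values, rep(900 / 45, 50), tolerance = 1e-9)

  # at Kd the ratio is (1 + 1/Rf)/2
  k <- simulate_er_gcamp_trace(rep(150, 10), calib, fmax_level = 1000)
  expect_equal(k$trace$values[1], 1000 * (1 + 1 / 45) / 2, tolerance = 1e-9)

  # ionomycin saturates
  io <- simulate_er_gcamp_trace(rep(130, 100), calib, fmax_level = 1000,
                                ionomycin_onset = 60)
  expect_true(all(io$trace$values[61:100] == 1000))

  expect_error(simulate_er_gcamp_trace(c(-1, 0)), ">= 0")
})

test_that("caffeine refill trace follows the programmed exponential", {
  s <- simulate_caffeine_refill(1, 274.1, duration_s = 300)
  at <- function(tt) s$values[which(s$time_s == s$washout_time_s + tt)]
  expect_equal(at(0), 0)
  expect_equal(at(190), 1 - exp(-190 / 274.1))

  # zero depth: constant 1
  s0 <- simulate_caffeine_refill(0, 100)
  expect_true(all(s0$values == 1))

  # tau -> 0 limit: immediate recovery after washout
  sf <- simulate_caffeine_refill(1, 0)
  post <- s$time_s > sf$washout_time_s
  expect_true(all(sf$values[post] == 1))
})

test_that("FRAP generator matches its closed form and round-trips the fit", {
  s <- simulate_frap_trace(0.8, 30, 1)
  nf <- normalize_frap(s$trace)
  # value at 180 s: linear interpolation of 0.8 * (1 - exp(-t/30))
  expect_equal(recovery_at(nf, 180), 0.7980061, tolerance = 1e-6)
  # immediately post-bleach, full bleach: zero
  expect_equal(recovery_at(nf, 0), 0)

  fit <- fit_recovery(nf)
  expect_true(fit$converged)
  expect_equal(fit$mobile_fraction, 0.8, tolerance = 0.01)
  expect_equal(fit$tau_s, 30, tolerance = 0.01 * 30)
})

test_that("grouped-measurement generator builds the nested structure", {
  d <- simulate_grouped_measurements(c(a = 1, b = 3), c(0, 10), 0, 4, seed = 1)
  expect_equal(nrow(d), 2 * 2 * 4)
  expect_setequal(unique(d$group), c("a", "b"))
  expect_setequal(unique(d$culture), c("c1", "c2"))
  # zero residual: values are exactly mean + offset
  expect_equal(sort(unique(d$value)), c(1, 3, 11, 13))

  # one culture: no culture structure in the values
  d1 <- simulate_grouped_measurements(c(a = 0, b = 0), 5, 0, 3, seed = 2)
  expect_true(all(d1$value == 5))
})
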
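# vesiflux

Quantitative analysis of live-cell fluorescence imaging of neuronal
secretion and endoplasmic-reticulum (ER) physiology, with a synthetic-data
generator that makes every stage of the pipeline verifiable against known
ground truth.

The package is aimed at labs doing pHluorin-based exocytosis imaging and
genetically encoded Ca²⁺ indicator work in cultured neurons. It covers:

* **Dense-core-vesicle (DCV) exocytosis** — NPY-pHluorin fusion events are
  detected as rapid punctum appearances: candidate sites from
  difference-image spot detection, then per-site validation on 3×3-pixel
  ROI traces with the amplitude criterion *F ≥ F₀ + 2·SD(F₀)* and a rise
  time < 1 s. The total vesicle pool is counted as the number of puncta
  during NH₄Cl dequenching, and the released fraction is
  events / pool.
* **Synaptic-vesicle (SV) exocytosis** — SypHy synapses (6×6-pixel ROIs at
  NH₄Cl-responsive puncta) are classified active when
  max ΔF/F₀ ≥ 3·SD(F₀)/F₀ during stimulation; the fused fraction is
  ΔF_stim / ΔF_NH₄Cl and endocytosis is the decay constant τ of
  *A·e^(−t/τ) + C* fitted over 60 s post-stimulation.
* **ER Ca²⁺** — the ER-GCaMP6-150 calibration
  *[Ca²⁺]₍ER₎ = K_d·[(F_r/F_max − 1/R_f)/(1 − F_r/F_max)]^(1/n)* with
  K_d = 150 µM, R_f = 45, n = 1.6, its exact algebraic inverse, caffeine
  store-depletion peak/AUC metrics, and refill recovery at T = 190 s after
  washout.
* **FRAP** — normalization to the mean of 10 prebleach frames, recovery at
  a chosen time (linear interpolation), and exponential recovery fits for
  mobile fraction and τ.
* **Nested statistics** — the culture-nested ANOVA model comparison
  (`y ~ group + culture` vs `y ~ culture`), Tukey-adjusted contrasts of
  culture-adjusted group means, one-sample t-tests, a robust FDR outlier
  screen (flags only), and the proteomics significance filter
  (|log2FC| > 0.56 and q < 0.01, strict).

Every analysis has a simulator counterpart (`simulate_dcv_movie()`,
`simulate_syphy_traces()`, `simulate_er_gcamp_trace()`,
`simulate_caffeine_refill()`, `simulate_frap_trace()`,
`simulate_grouped_measurements()`) that emits exact ground truth, so
detection thresholds, normalization and pool counting can be shown to be
unbiased without any raw data.

## Worked example

Simulate one control neuron (60-vesicle pool, on average 12 fusion events
during a 16×50-AP train at 50 Hz, peak SNR 8 at 2 Hz sampling) and run the
full detection pipeline:

```r
library(vesiflux)

sim <- simulate_dcv_movie(dcv_sim_params(seed = 7))
sim$movie
#> <time_lapse_movie: 120 frames of 64x64 px, dt = 0.5 s (60 s total), 200 nm/px>
#> <stimulation_protocol 'DCV_TRAIN': 16 burst(s) of 50 pulses at 50 Hz, t0 = 10 s>
#> <perfusion_schedule>
#>   NH4Cl:      [45, 60) s
#>   ionomycin:  none
#>   caffeine:   none

res <- analyze_dcv_movie(sim$movie)
res
#> <cell_fusion_summary: 13 events, pool 60, fused fraction 0.217>
nrow(sim$truth$events)   # ground truth
#> [1] 13
```

All 13 programmed events are recovered and the NH₄Cl pool is counted
exactly; `res$events` holds per-event onset, peak ΔF/F₀ and rise time, and
`plot(res)` draws the cumulative fusion-event curve aligned to the
stimulation onset.

The ER Ca²⁺ calibration round-trips through a synthetic indicator trace
with an ionomycin saturation at 180 s:

```r
calib <- er_calibration()        # Kd 150 uM, Rf 45, Hill n 1.6
er <- simulate_er_gcamp_trace(rep(130, 240), calib, fmax_level = 1200,
                              ionomycin_onset = 180)
estimate_er_calcium(er$trace, rest_window = c(0, 60),
                    ionomycin_window = c(180, 240), calib)
#> [1] 130.0002
```

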
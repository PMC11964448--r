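---
title: "vesiflux: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vesiflux: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiflux)
```

This vignette is the package's own account of the science it implements:
the measurement models, the conventions that make the numbers
reproducible, and the choices made where the underlying procedures were
genuinely open. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Coordinates, time and windows

All pixel coordinates are 0-based `(y, x)` pairs; frame `i` (0-based) sits
at time `i * frame_interval_s`, so frame 0 is t = 0. Time windows used to
*select frames* (stimulation epochs, perfusion windows) are half-open
`[start, end)`; windows used to *integrate* a signal (AUC metrics) are
closed, so that abutting windows tile additively
(`auc[a,b] + auc[b,c] = auc[a,c]` exactly under the trapezoid rule). Odd
ROI sides are centred; the 6×6 synapse ROI anchors its top-left corner at
`center - (2, 2)`, a fixed convention so even-sided ROIs are
deterministic. Baseline statistics (F₀ and its SD) use the first 10 frames
with sample (n−1) normalization.

## DCV fusion detection

A fusion event dequenches the pHluorin lumen and a punctum appears within
a frame or two. The detector works in two stages.

**Candidate sites.** Each frame in the stimulation-to-NH₄Cl interval is
compared with the pixelwise median of its three preceding frames; the
difference image is smoothed (σ = 1 px) and spot-detected at 5 robust
noise units (median/1.4826·MAD of the smoothed difference). Detections
within 3 px across frames are one site; repeated detections at a site
within 2 frames are one appearance ("firing"). The 5-unit threshold on a
*difference* image is deliberately stricter than the 4-unit threshold used
for static puncta: after smoothing, a 64×64 frame offers a few hundred
independent chances per frame for a false maximum, and 5 units keeps the
expected number of noise sites per movie far below one.

**Event validation.** Each site yields a 3×3 ROI trace, normalized to the
first 10 frames. A firing at frame f is a fusion event if the trace
reaches `F0 + k·SD(F0)` (default k = 2; with a noiseless baseline the
threshold degenerates, so a floor of 1e−6·F₀ applies) and the rise
completes in under 1 s (strict). The rise time is measured from the frame
before the firing to the first noise-tolerant local peak — the climb
continues only while the next frame improves on the running peak by more
than one baseline-SD step, so a single noisy up-tick does not extend the
measured rise. Anchoring validation at the firing frames, rather than
running a threshold state machine over the whole trace, has one important
property: the slow fluorescence tail that a neighbouring event leaks into
a site's ROI cannot hold the state machine above threshold and mask a
genuine rapid appearance, and conversely baseline noise crossings far from
any detected appearance are never promoted to events.
`detect_fusion_events()` remains available as the standalone trace-level
state machine (crossing, noise-tolerant peak, strict re-arm below
threshold) for users analysing traces without movies.

The amplitude criterion is read as *F ≥ F₀ + 2·SD(baseline F)*. The
literal alternative — the ratio F/F₀ exceeding "2 SD" — is dimensionally
inconsistent (a pure number compared against an intensity), and the
chosen reading is the only one under which the criterion scales correctly
with the camera gain. The multiplier is a parameter.

**Pool counting.** The total vesicle pool is the number of puncta in the
mean projection over the NH₄Cl plateau, taken as the last 50% of the
NH₄Cl window to skip the wash-in ramp (whether the original analyses used
one frame or a projection is not documented; a projection is the
lower-variance choice). `detect_puncta()` flattens the smoothed image
against a local median background (radius 4 px) before thresholding at
4 robust-noise units: a global median/MAD threshold fails in crowded
fields, where puncta flanks inflate the apparent noise, while the local
background keeps the threshold honest from empty fields up to ~120
puncta in a 128×128 field. Detections are thinned greedily (descending
intensity, ties row-major) to a 3 px minimum separation.

**Fused fraction.** The default denominator is the total NH₄Cl pool.
The alternative convention — events relative to the pool *remaining*
after stimulation (`denominator = "remaining"`) — is available because
both conventions circulate; results reported by this package always state
the default unless the flag is set. A pool of zero with detected events
flags the fraction as undefined rather than clipping.

## SV (SypHy) analysis

Synapses are identified as puncta in (mean NH₄Cl plateau − mean of the
10 frames preceding NH₄Cl); each gets a 6×6 ROI. A synapse is *active*
when max ΔF/F₀ during stimulation reaches 3·SD(F₀)/F₀ (inclusive). The
stimulation maximum for the fused fraction is searched over the window
plus a 2 s margin, because the peak of a 5 s/40 Hz response regularly
falls on the first post-stimulus frame at 2 Hz sampling. The endocytosis
fit includes an offset C (incomplete retrieval leaves a plateau; the
original fit form is unstated, and omitting C biases τ upward whenever a
plateau exists). Per-neuron pooling rescales each active synapse from
baseline 0 to NH₄Cl maximum 1 before averaging.

## ER Ca²⁺ calibration

The calibration inverts the indicator's Hill saturation curve:

$$[\mathrm{Ca}^{2+}]_{ER} = K_d\left(\frac{F_r/F_{max} - 1/R_f}
{1 - F_r/F_{max}}\right)^{1/n},\qquad K_d = 150\ \mu M,\ R_f = 45,\ n = 1.6.$$

The printed form of this equation is typographically ambiguous about what
the exponent 1/n applies to; it is resolved here as an outer exponent on
the whole bracket — the standard Hill inversion, and the only reading
under which K_d is the half-saturation point (the bracket equals 1 exactly
half-way between the indicator floor 1/R_f and saturation). Fixed points:
0 µM at r = 1/R_f, K_d at r = (1+1/R_f)/2, log–log slope n between bracket
and concentration. The forward map `ratio_for_concentration()` is the
exact algebraic inverse (round trip < 1e−9 relative over 0–500 µM).

F_max is the mean over the last 50% of the ionomycin window (wash-in
skipped), and no pH correction is applied to F_max, mirroring the
original protocol. Caffeine concentrations and timings are treated as
metadata only. Refill recovery at T after washout is
`(F(washout+T) − depleted)/(baseline − depleted)` with linear
interpolation between frames.

## FRAP

Normalization is F/F₀ with F₀ the mean of the 10 prebleach frames; the
post-bleach clock starts at the first post-bleach frame. Whether
published "percent recovery" values are F/F₀ or floor-rescaled is often
unstated; the default here is F/F₀ (under a complete bleach the two
coincide), with full-scale rescaling behind a flag. The recovery fit is
`floor + mobile·(1 − exp(−t/τ))`; an exactly flat post-bleach trace is
reported as mobile fraction 0 with τ undefined rather than a fit failure.

## Statistics

Measurements are neurons (n) nested in independent cultures (N). The
group effect is tested by comparing the fixed-effect linear models
`value ~ culture` and `value ~ group + culture` with an F-test on
residual sums of squares; with one culture this reduces *exactly* to the
classical one-way ANOVA (asserted to 1e−10 in the tests). A culture
perfectly aliased with a group is an error, not a silent drop. The
degenerate zero-residual case (identical group means, no noise) returns
F = 0, p = 1 explicitly. Post-hoc contrasts are Tukey-adjusted estimated
marginal means of the same model. The outlier screen is a documented
simplification of proprietary robust-regression screens — median/MAD
studentization with a Benjamini–Hochberg gate — and it only flags, never
removes; it is opt-in and no analysis in this package applies it by
default. The proteomics filter keeps |log2FC| > 0.56 AND q < 0.01, both
strict (the source thresholds do not state strictness; strict is chosen
so a protein sitting exactly on a threshold is excluded) and two-sided,
since both up- and downregulated proteins count.

## The synthetic-data generator

The generator's defaults are the study conditions of the assays it
emulates:

* DCV: 60-vesicle pool, Poisson mean 12 fusion events per cell during a
  16-burst train of 50 APs at 50 Hz, event peak amplitude ΔF/F₀ = 0.5 on
  a baseline of 100 counts with noise SD 6.25 (peak SNR 8), PSF σ = 1 px
  at 200 nm pixels, NH₄Cl window after the train. The fusion-imaging
  frame rate and movie duration are not documented in the source
  protocols; 2 Hz and 60 s are declared package defaults, not inferred
  values.
* SV: single 5 s epoch at 40 Hz, programmed fused fraction
  `stim_amplitude / nh4cl_amplitude`, exponential re-acidification.
* ER-GCaMP: the exact forward model of the calibration (so estimation is
  inverse∘forward, an identity to 1e−6 on noiseless traces), ionomycin
  saturation at F_max.
* Refill: `1 − depth·exp(−t/τ)` after washout; τ = 274.1 s makes the
  50%-at-190 s readout an analytic fixed point.
* FRAP: 10 prebleach frames every 8.5 s, 300 s of recovery.
* Grouped measurements: value = group mean + culture offset + Gaussian
  residual, balanced.

Two generator choices deserve explanation. First, an event's rise is
rendered starting at the first frame at or after its onset
(frame-integrated appearance): a camera integrating over an exposure
reports a sub-frame onset as a step between two frames, and rendering the
rise on the frame grid keeps the measured rise time of a genuinely fast
event below the 1 s cutoff regardless of onset phase. Second, vesicles
are placed with a 4 px minimum separation: two equal puncta with a 1 px
PSF merge into a single smoothed peak below ~3.5 px separation (the
midpoint becomes brighter than either peak after σ = 1 smoothing), so
4 px is the closest packing at which "count the puncta" is a well-posed
ground truth. Both are properties of the emulated measurement, not tuning
knobs.

Per-movie randomness is split into independent streams (placement, event
timing, noise) derived from one seed via `derive_seeds()`, so identical
seeds give bit-identical movies. The event-rate multiplier *thins* a
shared base Poisson draw — marginally the count is exactly
Poisson(mean × multiplier), but under a shared seed a manipulated
condition's events are a subset of its control's. Condition-comparison
studies (e.g. the 30-cell-per-condition simulations in
`scripts/acceptance.R`) exploit this as a paired common-random-number
design: the percent-reduction estimate then has binomial rather than
two-independent-Poisson variance, roughly halving its SD at the same
number of cells.

What the generator does **not** emulate: photobleaching during
acquisition, focal drift, pH kinetics of pHluorin beyond on/off
dequenching, shot-noise statistics by default (additive Gaussian is the
EM-CCD regime proxy; `noise_model = "poisson"` is available), optical
aberrations, or spatially structured backgrounds (neurite masks are
uniform fields). Passing tests therefore demonstrate that the *analysis*
is unbiased under the stated noise model — not that it is robust to
every artefact of real recordings.

## Problem sizes and numerical choices

Simulation-backed tests use 64×64 fields, 120-frame movies, 20–30 seeds
for stochastic properties and 30 cells per condition for the
effect-recovery studies; pool-counting accuracy at 120 vesicles uses a
128×128 field, matching the density of a real soma rather than packing an
unphysical field. These sizes were chosen to put the Monte-Carlo error
well inside each asserted tolerance. Thresholds that would otherwise
degenerate carry explicit floors (1e−6·F₀ for the noiseless amplitude
criterion, 1e−12 robust-noise floor in spot detection); ties in peak
ordering break row-major; interpolation is linear everywhere a value is
read between frames.

## Known limitations

Site localization is pixel-level (no sub-pixel fitting), so site-to-truth
matching tolerances are 1–2 px. Crowded fields bias event counts
slightly downward (simultaneous nearby appearances can be suppressed as
one detection); at the default density this loss is under ~2% and cancels
in condition ratios. The nested ANOVA treats culture as a fixed effect —
the model-comparison convention it implements — not a random effect;
linear mixed models are out of scope. ROUT-style outlier removal is
deliberately not reproduced, only approximated by a flag-only screen.
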
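---
title: "Quantifying stimulus-evoked calcium responses: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stimulus-evoked calcium responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evokedca)
```

## The problem

Two-photon imaging of GCaMP6s-expressing cortical neurons in awake,
head-fixed mice yields fluorescence movies in which a brief peripheral
stimulus (for example a 30 V, 200 ms electrical pulse to the hindpaw)
evokes calcium transients in a subset of cells. Turning those movies into
population numbers — what fraction of layer-5 spino-cortical recipient
neurons responds, how fast, and how that compares with layer-4 neurons —
requires a chain of deterministic processing steps, each with choices that
affect the result. This package implements that chain and pairs every step
with seeded synthetic data whose ground truth is known, so the whole
pipeline can be validated quantitatively rather than by eye.

## Motion correction

Awake-preparation movies drift in x–y relative to the objective. Each frame
is realigned to a reference image by the integer pixel translation that
maximizes the zero-normalized cross-correlation (NCC) with the reference,
searched exhaustively over `[-max_shift, max_shift]^2` (default 20 px,
which bounds the search at a cost of `41^2` correlations per frame). NCC
ties are broken toward the smallest shift norm, then lexicographically, so
the estimator is deterministic. Because the correlation is zero-normalized,
the estimate is invariant to positive affine changes of frame intensity
(laser power drift, photobleaching trends within a frame).

The reference is the average of the *stable* frames. Stability is not an
observable, so we use a two-pass proxy: pass 1 averages all frames and
scores each frame's zero-shift NCC against that mean; pass 2 averages the
top `stability_quantile` (default 0.8) of frames. For sessions that are
mostly stationary with occasional jumps — the regime rigid correction is
suited to — the retained set is dominated by the modal head position and
the reference converges to the true scene, which is what the exact-recovery
tests exploit.

Three deliberate restrictions: translation only (no rotation or non-rigid
warp), integer shifts only (intensities are never interpolated, so ROI
statistics are computed on raw values), and exposed borders after
translation are marked invalid (`NA`) rather than zero-filled, so ROI means
are never contaminated by padding. Frames whose peak NCC falls below
`score_floor = 0.3` are flagged low-confidence but kept; silently dropping
frames would corrupt the time base. Pixel coordinates are 1-based
throughout, the R convention; shifts are coordinate-free integers.

## Traces, baseline, and ΔF/F

ROI fluorescence is the plain mean over the ROI's valid pixels per frame;
ROIs come from a label image or from polygons rasterized by pixel-center
inclusion. Each sample is stamped with its frame *start* time
(`origin_time + (k-1) * frame_period`), matching how stimulus onsets are
marked on the acquisition clock.

The per-trial baseline `F0` is the mean fluorescence over the 10 s
preceding the trial onset, as a half-open window `[onset - 10 s, onset)`:
the onset sample belongs to the response epoch, never to the baseline, so
`F0` cannot be contaminated by stimulus-locked signal. Recordings that
start less than 10 s before a trial use what exists and carry a truncation
flag. ΔF/F is `(F - F0)/F0`, exactly gain-invariant and with documented
offset behavior (`(F - F0)/(F0 + b)` under a common additive offset `b` —
background subtraction therefore matters before normalization, and both
properties are tested).

Line-scan recordings (ms-scale revisiting of selected cells) enter as CSV
with a declared sample period (default 1 ms) and flow through the same
baseline and ΔF/F code path; no smoothing is ever applied.

## Response detection and latency

A cell is *responsive* in a trial when its ΔF/F reaches 10% above baseline
(`threshold = 0.10`) for at least `min_consecutive` consecutive valid
samples within `(onset, onset + response_window]`. Defaults: window 2000 ms
and 2 consecutive samples at 33.3 ms frames; window 500 ms and 5 samples
for 1-kHz line scans. The consecutive-sample guard suppresses single-sample
noise crossings; masked samples break a run. The guard is not a full noise
model: with ~60 window samples and Gaussian ΔF/F noise of SD 0.02, cells
whose true peak sits within about 0.02 of the threshold still cross it with
appreciable probability, so threshold classification has a soft edge of
roughly that width. This matters when responder fractions are small (see
validation below) and is a property of any fixed-threshold rule at this
noise level, not of the implementation.

Latency is the interval from stimulus onset to the threshold crossing that
opens the qualifying run. By default the crossing time is linearly
interpolated between the last sub-threshold and first at/above-threshold
samples, which recovers sub-sample accuracy: with a saturating rise
`1 - exp(-(t - L)/tau_r)` (rise constant 20 ms) the 0.10 crossing sits at
`L + 20 ln(10/9) ≈ L + 2.107 ms`, and the interpolated estimator lands
within 0.01 ms of that at 1-kHz sampling. The uninterpolated first-sample
rule is available for audit. Latency is exactly equivariant under onset
shifts and invariant to intensity rescaling (the threshold is relative).

Per-ROI classification across repeated trials uses a majority rule
(responsive in at least half of determinate trials). Responder fractions
are computed per field of view and summarized as mean ± SEM across fields,
which is how imaging studies report "percentage of responding neurons" with
n = fields.

Population latency structure is summarized two ways: modes of a Gaussian
kernel density estimate (bandwidth 5 ms on a 1-ms grid over
`[0, max + 3·bandwidth]`; modes are strict local maxima at ≥ 20% of the
tallest peak, which ignores shoulder ripples without hiding genuine minor
components), and a two-sample Kolmogorov–Smirnov comparison. The KS `D` is
computed exactly at the pooled sample points and checked in the tests
against an exhaustive ECDF oracle and against `stats::ks.test`; the p-value
uses the asymptotic Kolmogorov series with effective size
`n_a n_b / (n_a + n_b)`. The headline speed comparison is the percent
reduction in *mean* latency of the faster population; means rather than
medians, because a two-point 40/70 ms mixture has a degenerate median.

## Fold change

Terminal-activation experiments are quantified as the ratio of window
means, `mean(post)/mean(pre)`, so "1.4-fold increase" means post/pre = 1.4
(not pre + 1.4×). The pre-window mean must be positive.

## Behavioral scoring

Three deterministic rules: the von Frey threshold is the lowest filament
force evoking a response on ≥ 3 of 5 applications (ascending series; if no
filament qualifies the highest supplied force is returned, censored — the
record itself defines the ceiling); foot-shock escape latency is the first
escape frame divided by the 30 frames/s camera rate, exact rational
arithmetic; and latency assays are clamped at their protective cutoffs
(Hargreaves 20 s, hot plate 30 s, beam 60 s) with an explicit censored flag
rather than dropped trials, so downstream means are reproducible.

## The synthetic generators

The generators exist to give every analysis step a ground truth. A
transient is `A · (1 - e^{-(t-L)/τ_r}) · e^{-(t-L)/τ_d}` with rise
`τ_r = 20 ms` and decay `τ_d = 1500 ms` by default — GCaMP6s-like scales
chosen once as generator constants, exposed in the config. The trace and
movie generators divide the kernel by its analytic peak factor so that a
drawn amplitude *is* the peak ΔF/F; this keeps amplitude distributions
interpretable against the detection threshold. Traces are
`F0 (1 + signal) + N(0, (0.02 F0)^2)` on a trial schedule of independent
epochs (10-s baseline + 2-s window each), which emulates inter-trial
intervals long enough for full indicator decay. Movies render Gaussian
soma blobs (radius 6 px) on a constant background at the acquisition grid
(512 × 512 by default, downscaled in tests for speed), apply a rigid
per-frame shift path, and add noise; ROI masks are the blob supports, and
the emitted truth carries the shift path, responder flags, amplitudes,
onsets, and noiseless ROI-mean traces.

Responder structure can be fixed flags or an amplitude distribution. The
exponential model is calibrated against the threshold analytically:
`P(A ≥ 0.10) = exp(-0.10/mean)`, giving ≈ 24.9% at mean 0.072 and ≈ 5.0%
at mean 0.0334 — the two populations' reported responder levels. Latency
populations are Gaussian mixtures truncated at zero: 40/70 ms components
(weights 0.68/0.32) versus a single 70 ms component reproduce both the
bimodal/unimodal mode structure and, via mixture-mean arithmetic
(`0.68·40 + 0.32·70 = 49.6`), a ≈ 29% reduction in mean latency.

What the generators do *not* emulate: neuropil contamination, bleaching,
shot noise (a Gaussian model stands in), non-rigid or within-frame motion,
overlapping cell bodies, and spike-to-calcium nonlinearity. Passing tests
therefore certify the analysis chain — registration, normalization,
detection, latency, statistics — under rigid motion and additive noise, not
segmentation quality or biophysical realism on real movies.

## Numerical choices and degenerate inputs

NCC is undefined for constant frames; such frames get shift (0, 0) and an
`NA` score rather than an arbitrary number. A single-frame movie is its own
reference, with a warning. Baselines of zero or negative mean, empty ROIs,
out-of-grid ROIs, unknown assay labels, and non-increasing filament series
are hard errors — they signal broken inputs, not edge cases to paper over.
Fully masked response windows give an *indeterminate* call, excluded from
majority voting. KDE mode calling needs at least 5 latencies. All
generators reset the RNG from their config seed, so identical configs give
byte-identical CSV output.

## Validation scale

The shipped tests and the acceptance script run the full operating point at
desk scale: 7 fields × 40 ROIs × 3 trials per population for responder
fractions, 92- and 39-sample latency populations, 200-sample fold-change
windows, 200 seeded simulations for the unbiasedness property, and movie
fixtures of 48 × 48 px. These sizes were chosen so the complete validation
suite runs in well under a minute while keeping Monte Carlo error small
relative to the tolerances being asserted; all of them scale up through the
same configs.

## Running the pipeline

```{r, eval = FALSE}
config <- list(
  seed = 1,
  input = list(mode = "synthetic_movie",
               scene = list(n_rois = 20, grid_shape = c(128, 128),
                            motion_path = "random_walk")),
  params = list(threshold = 0.10, window_ms = 2000, max_shift = 20)
)
report <- run_pipeline(config, "run1")
report$populations[[1]]$responder_fraction
```

Every stage writes its artifact (`shifts.csv`, `reg.tif`, `traces.csv`,
`dff.csv`, `calls.csv`, `truth.json`, `report.json`), the report embeds the
config hash, seed, and package version, and deterministic stages reproduce
the report bit-for-bit. A thin command-line wrapper lives at
`system.file("scripts/pipeline.R", package = "evokedca")`.
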
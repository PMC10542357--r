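# evokedca

Quantification of stimulus-evoked calcium responses in two-photon imaging
of cortex, plus deterministic scoring of the accompanying nociceptive
behavioral assays.

The scientific setting: GCaMP6s-expressing cortical neurons — layer-5
spino-cortical recipient neurons versus layer-4 neurons — are imaged in
awake mice while brief electrical stimuli are delivered to the hindpaw. The
analysis questions are (i) what fraction of each population responds, (ii)
with what latency, and (iii) whether the two populations' latency
distributions differ. Answering them takes a chain of processing steps that
this package implements end to end, together with seeded synthetic-data
generators with machine-readable ground truth so every step is validated
against known answers.

## What it computes

* **Rigid motion correction.** Each frame is realigned to a stable-frame
  reference (average of the top 80% of frames by correlation with the
  session mean) by the integer x–y translation maximizing the
  zero-normalized cross-correlation, searched exhaustively over
  ±`max_shift` px. Exposed borders become invalid pixels, never zeros.
* **ΔF/F on a per-trial baseline.** ROI traces are plain pixel means;
  `F0` is the mean over the half-open 10-s window before each trial onset;
  `ΔF/F = (F − F0)/F0`.
* **Responder classification and latency.** A cell is responsive when
  ΔF/F ≥ 0.10 (10% above baseline) for ≥ 2 consecutive frames (≥ 5
  line-scan samples) in the post-stimulus window; latency is the
  linearly-interpolated threshold-crossing time minus the stimulus onset.
  Per-ROI calls across trials use a majority rule; fractions are reported
  as mean ± SEM across fields of view.
* **Population statistics.** Gaussian-KDE latency modes (bandwidth 5 ms),
  percent reduction in mean latency between populations, and a two-sample
  Kolmogorov–Smirnov test (`D = sup |ECDF_a − ECDF_b|`, asymptotic p with
  effective n = n_a·n_b/(n_a+n_b)).
* **Fold change.** Post/pre window-mean ratio for terminal-activation
  experiments.
* **Behavior.** von Frey threshold (lowest force with ≥ 3 of 5 responses),
  foot-shock escape latency (first escape frame / 30 fps), and cutoff
  censoring (Hargreaves 20 s, hot plate 30 s, beam 60 s).

## Worked example

Simulate a layer-5-like field (40 ROIs, 3 trials, transient peak ΔF/F
drawn Exponential with mean 0.072, noise SD 0.02·F0), then classify:

```r
library(evokedca)

cfg <- scene_config(n_rois = 40, n_trials = 3,
                    amplitude = list(dist = "exponential", mean = 0.072),
                    seed = 1)
sim   <- simulate_traces(cfg)
dff   <- dff_by_trial(sim$traces, sim$trials)
calls <- call_responses(dff, sim$trials)
responder_fraction(calls)
#>   population n_rois n_fields responder_fraction sem
#> 1 population     40        1               0.25  NA
```

A quarter of the ROIs qualify — the analytic expectation for this
amplitude model is `exp(-0.10/0.072) ≈ 0.249`. Latency needs the
higher-rate line-scan mode (1-kHz sampling on responsive cells), here with
transient onsets drawn from a 40/70 ms bimodal mixture:

```r
cfg <- scene_config(n_rois = 92, n_trials = 1, frame_period = 1,
                    window_ms = 500, amplitude = 1, tau_d = Inf,
                    onset_latency = latency_mixture(c(37.9, 67.9),
                                                    c(0.68, 0.32), 3),
                    seed = 2)
sim   <- simulate_traces(cfg)
dff   <- dff_by_trial(sim$traces, sim$trials, window_ms = 500)
calls <- call_responses(dff, sim$trials, response_window = 500,
                        min_consecutive = 5)
latency_modes(calls$latency_ms, bandwidth = 5)
#> <mode_estimate> modes at 40, 71 ms (bw 5 ms)

l4 <- simulate_latencies(latency_mixture(70, 1, 3), 39, seed = 3)
cmp <- compare_latency_populations(calls$latency_ms, l4)
```

which prints a mean latency of 50.5 ms against 69.7 ms for the unimodal
comparison population — a 27.6% reduction, KS D = 0.65, p ≈ 1.5e-10. The
two KDE modes sit at the mixture components (each transient crosses the
10% threshold ≈ 2.1 ms after its onset, so onsets at 37.9/67.9 ms yield
40/70 ms latencies).

`run_pipeline()` chains registration → extraction → ΔF/F → classification
from a single config (list or YAML), writes every intermediate artifact,
and emits a JSON report with the config hash and seed; see the methods
vignette (`vignettes/evoked-calcium-methods.Rmd`) for the full model
description and design rationale.

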
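Package: evokedca
Title: Evoked Calcium Imaging Analysis: Registration, dF/F, Latency and
    Behavior Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification pipeline for stimulus-evoked two-photon calcium
    imaging in cortex: rigid x-y motion correction by exhaustive normalized
    cross-correlation against a stable-frame reference, ROI fluorescence
    extraction, per-trial dF/F with a 10-s pre-stimulus baseline,
    threshold-crossing (10% above baseline) responder classification and
    latency estimation, latency-distribution mode analysis and two-sample
    Kolmogorov-Smirnov comparison, post/pre fold-change quantification, and
    deterministic scoring of nociceptive behavioral assays (von Frey 3-of-5
    rule, foot-shock escape latency, cutoff censoring). Includes seeded
    synthetic-data generators with machine-readable ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
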
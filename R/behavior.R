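#' Behavioral assay scoring
#'
#' Deterministic scoring rules for the nociceptive assays: graded von Frey
#' filaments (mechanical threshold), foot-shock escape latency from video
#' frames, and protective cutoff censoring for latency assays.
#'
#' @name behavior
NULL

# Protective cutoffs per assay, seconds.
assay_cutoffs <- c(hargreaves = 20, hotplate = 30, beam = 60)

#' von Frey mechanical threshold
#'
#' Filaments are applied in increasing force order, each `n_trials` times
#' (5). The mechanical response threshold is the lowest force evoking a
#' response on at least `criterion` of the applications (3 of 5). When no
#' filament qualifies, the highest supplied force is returned with the
#' censored flag set.
#'
#' @param forces filament forces in grams, strictly increasing.
#' @param responses response counts per filament, each in `[0, n_trials]`.
#' @param criterion minimum responses to qualify (default 3).
#' @param n_trials applications per filament (default 5).
#' @return list: `threshold_g`, `censored`.
#' @export
von_frey_threshold <- function(forces, responses, criterion = 3L,
                               n_trials = 5L) {
  if (length(forces) == 0) stop("empty von Frey record")
  stopifnot(length(forces) == length(responses), criterion <= n_trials)
  if (any(diff(forces) <= 0)) stop("forces must be strictly increasing")
  if (any(responses < 0 | responses > n_trials)) {
    stop(sprintf("responses must lie in [0, %d]", n_trials))
  }
  hit <- which(responses >= criterion)
  if (length(hit) == 0) {
    list(threshold_g = forces[length(forces)], censored = TRUE)
  } else {
    list(threshold_g = forces[hit[1]], censored = FALSE)
  }
}

#' Foot-shock escape latency from video frames
#'
#' The first frame on which the mouse begins to escape, divided by the
#' camera rate (30 frames/s), gives the escape latency. A missing escape
#' frame (`NA`) is censored at the trial length.
#'
#' @param first_escape_frame integer frame index (>= 0; frame 0 is the shock
#'   onset frame), or `NA` when no escape occurred.
#' @param fps camera frame rate (default 30).
#' @param trial_length_s censoring value for trials without an escape.
#' @return list: `latency_s`, `censored`.
#' @export
escape_latency <- function(first_escape_frame, fps = 30,
                           trial_length_s = NA_real_) {
  if (fps <= 0) stop("fps must be positive")
  if (is.na(first_escape_frame)) {
    if (is.na(trial_length_s)) stop("no escape frame and no trial length")
    return(list(latency_s = trial_length_s, censored = TRUE))
  }
  if (first_escape_frame < 0) stop("first_escape_frame must be >= 0")
  list(latency_s = first_escape_frame / fps, censored = FALSE)
}

#' Clamp a latency at the assay's protective cutoff
#'
#' Cutoffs: Hargreaves 20 s, hot plate 30 s, beam walk 60 s. The reported
#' latency is `min(raw, cutoff)`; the censored flag marks clamped values.
#' Idempotent: re-applying the cutoff never changes a clamped value.
#'
#' @param raw_latency_s raw latency, seconds (>= 0).
#' @param assay one of `"hargreaves"`, `"hotplate"`, `"beam"`.
#' @return list: `latency_s`, `cutoff_s`, `censored`.
#' @export
apply_cutoff <- function(raw_latency_s, assay) {
  if (!assay %in% names(assay_cutoffs)) {
    stop(sprintf("unknown assay '%s' (use %s)", assay,
                 paste(names(assay_cutoffs), collapse = ", ")))
  }
  if (raw_latency_s < 0) stop("latency must be >= 0")
  cutoff <- assay_cutoffs[[assay]]
  list(latency_s = min(raw_latency_s, cutoff), cutoff_s = cutoff,
       censored = raw_latency_s >= cutoff)
}

#' Score a behavioral CSV table
#'
#' Three formats:
#' * von Frey: columns `animal, force_g, responses` (long, one row per
#'   filament) -> per-animal `threshold_g, censored`.
#' * escape: columns `animal, trial, first_escape_frame` -> per-trial
#'   `latency_s, censored`.
#' * latency: columns `animal, assay, raw_s` -> cutoff-censored latencies.
#'
#' @param tab data.frame, or path to a CSV file.
#' @param assay `"vonfrey"`, `"escape"`, or `"latency"`.
#' @param fps camera rate for escape scoring.
#' @return scored data.frame.
#' @export
score_behavior <- function(tab, assay = c("vonfrey", "escape", "latency"),
                           fps = 30) {
  assay <- match.arg(assay)
  if (is.character(tab)) tab <- utils::read.csv(tab)
  switch(assay,
    vonfrey = do.call(rbind, lapply(split(tab, tab$animal), function(d) {
      d <- d[order(d$force_g), ]
      r <- von_frey_threshold(d$force_g, d$responses)
      data.frame(animal = d$animal[1], threshold_g = r$threshold_g,
                 censored = r$censored)
    })),
    escape = {
      res <- lapply(seq_len(nrow(tab)), function(i) {
        escape_latency(tab$first_escape_frame[i], fps = fps)
      })
      data.frame(animal = tab$animal, trial = tab$trial,
                 latency_s = vapply(res, `[[`, numeric(1), "latency_s"),
                 censored = vapply(res, `[[`, logical(1), "censored"))
    },
    latency = {
      res <- lapply(seq_len(nrow(tab)), function(i) {
        apply_cutoff(tab$raw_s[i], tab$assay[i])
      })
      data.frame(animal = tab$animal, assay = tab$assay,
                 latency_s = vapply(res, `[[`, numeric(1), "latency_s"),
                 censored = vapply(res, `[[`, logical(1), "censored"))
    }
  )
}
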
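#' Synthetic data with ground truth
#'
#' Seeded generators emulating the study's statistical structure: GCaMP6s-like
#' stimulus-locked transients with population latency structure (bimodal
#' 40/70 ms for the layer-5 population, unimodal 70 ms for layer 4),
#' responder fractions set by an amplitude distribution interacting with the
#' 10% detection threshold, rigid x-y jitter, and additive Gaussian noise.
#' Every generator is fully deterministic under `(config, seed)` and emits
#' machine-readable ground truth alongside its data.
#'
#' @name synthetic_data
NULL

#' GCaMP-like transient kernel
#'
#' Saturating-rise / exponential-decay surrogate for a calcium transient:
#' 0 before the onset delay `onset`, and
#' `amplitude * (1 - exp(-(t - onset)/tau_r)) * exp(-(t - onset)/tau_d)`
#' afterwards (decay factor 1 when `tau_d = Inf`). With infinite decay the
#' kernel saturates at `amplitude`; with finite decay its peak is
#' `amplitude * kernel_peak_factor(tau_r, tau_d)`.
#'
#' @param t times, ms (vectorized).
#' @param amplitude peak scale, dimensionless dF/F.
#' @param tau_r rise time constant, ms (> 0).
#' @param tau_d decay time constant, ms (> 0, may be `Inf`).
#' @param onset delay from stimulus to transient start, ms.
#' @return dF/F values, same length as `t`.
#' @export
transient_kernel <- function(t, amplitude = 1, tau_r = 20, tau_d = Inf,
                             onset = 0) {
  stopifnot(amplitude >= 0, tau_r > 0, tau_d > 0)
  d <- t - onset
  out <- numeric(length(t))
  on <- d >= 0
  decay <- if (is.infinite(tau_d)) 1 else exp(-d[on] / tau_d)
  out[on] <- amplitude * (1 - exp(-d[on] / tau_r)) * decay
  out
}

#' Peak of the unit transient kernel
#'
#' Supremum over t of `(1 - exp(-t/tau_r)) * exp(-t/tau_d)`, attained at
#' `t* = tau_r * log(1 + tau_d/tau_r)`; equals 1 for infinite decay. The
#' trace generators divide by this factor so a drawn amplitude is the *peak*
#' dF/F regardless of kinetics.
#'
#' @inheritParams transient_kernel
#' @return peak factor in `(0, 1]`.
#' @export
kernel_peak_factor <- function(tau_r, tau_d) {
  if (is.infinite(tau_d)) return(1)
  tstar <- tau_r * log(1 + tau_d / tau_r)
  (1 - exp(-tstar / tau_r)) * exp(-tstar / tau_d)
}

#' Latency mixture specification
#'
#' A mixture of Gaussian components (truncated at 0) over response
#' latencies; `sigma = 0` gives point masses. The layer-5-like structure is
#' `latency_mixture(c(40, 70), c(0.68, 0.32), sigma)`; layer-4-like is a
#' single component at 70 ms.
#'
#' @param locations component centers, ms, sorted ascending.
#' @param weights component weights, non-negative, summing to 1.
#' @param sigma component SD, ms; scalar or one per component.
#' @return object of class `latency_mixture`.
#' @export
latency_mixture <- function(locations, weights = rep(1 / length(locations),
                                                     length(locations)),
                            sigma = 0) {
  stopifnot(length(locations) == length(weights))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("mixture weights must be non-negative and sum to 1")
  }
  if (is.unsorted(locations)) stop("locations must be sorted ascending")
  if (length(sigma) == 1) sigma <- rep(sigma, length(locations))
  stopifnot(all(sigma >= 0), length(sigma) == length(locations))
  structure(list(locations = locations, weights = weights, sigma = sigma),
            class = "latency_mixture")
}

#' Draw latencies from a mixture
#'
#' I.i.d. draws; Gaussian components are truncated at 0 by rejection.
#'
#' @param mix a [latency_mixture()].
#' @param n number of draws (>= 1).
#' @param seed RNG seed.
#' @return numeric vector of n latencies, ms.
#' @export
simulate_latencies <- function(mix, n, seed = 1) {
  stopifnot(inherits(mix, "latency_mixture"), n >= 1)
  set.seed(seed)
  comp <- sample.int(length(mix$locations), n, replace = TRUE,
                     prob = mix$weights)
  x <- stats::rnorm(n, mix$locations[comp], mix$sigma[comp])
  while (any(x < 0)) {
    bad <- x < 0
    x[bad] <- stats::rnorm(sum(bad), mix$locations[comp[bad]],
                           mix$sigma[comp[bad]])
  }
  x
}

#' Scene configuration for the trace and movie generators
#'
#' Defaults mirror the acquisition and analysis conditions: 33.3 ms/frame on
#' a 512 x 512 grid (downscalable), a 10-s pre-trial baseline, a 2-s
#' response window, additive Gaussian noise with SD a fraction 0.02 of F0,
#' and GCaMP6s-like kinetics (rise 20 ms, decay 1500 ms). Trials are
#' independent epochs of `baseline_ms + window_ms`: inter-trial intervals
#' are assumed long enough for full indicator decay, so no transient carries
#' into the next baseline.
#'
#' The responder model is either an amplitude distribution — e.g.
#' `list(dist = "exponential", mean = 0.072)`, whose interaction with the
#' 0.10 detection threshold yields an expected responder fraction
#' `exp(-0.10/mean)` (~25% at mean 0.072, ~5% at mean 0.0334) — or fixed
#' flags via `list(dist = "fixed", value = A, responder = <logical or
#' fraction>)`.
#'
#' @param n_rois number of ROIs / somata.
#' @param n_trials trials in the schedule.
#' @param frame_period ms per sample (33.3 frame scan; use 1 for line scan).
#' @param baseline_ms pre-onset baseline per trial.
#' @param window_ms response window per trial.
#' @param f0 baseline fluorescence (arbitrary units).
#' @param amplitude responder model (see Details).
#' @param onset_latency transient onset delay: scalar, one per ROI, or a
#'   [latency_mixture()] drawn once per ROI.
#' @param tau_r,tau_d kernel time constants, ms.
#' @param noise_sd_frac Gaussian noise SD as a fraction of `f0`.
#' @param grid_shape `c(rows, cols)` for movie rendering.
#' @param soma_radius soma radius in px (movie).
#' @param background background intensity (movie).
#' @param motion_path `NULL` (motionless), `"random_walk"`, or a matrix /
#'   data.frame of per-frame integer `(dx, dy)` content shifts (movie).
#' @param max_shift bound on motion-path shifts, px.
#' @param seed RNG seed; identical config + seed reproduce output exactly.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(n_rois = 40, n_trials = 3, frame_period = 33.3,
                         baseline_ms = 10000, window_ms = 2000, f0 = 100,
                         amplitude = list(dist = "exponential", mean = 0.072),
                         onset_latency = 40, tau_r = 20, tau_d = 1500,
                         noise_sd_frac = 0.02, grid_shape = c(512, 512),
                         soma_radius = 6, background = 20,
                         motion_path = NULL, max_shift = 20, seed = 1) {
  stopifnot(n_rois >= 1, n_trials >= 1, frame_period > 0, baseline_ms > 0,
            window_ms > 0, f0 > 0, tau_r > 0, tau_d > 0, noise_sd_frac >= 0)
  structure(as.list(environment()), class = "scene_config")
}

# Resolve per-ROI peak amplitudes and responder flags from the model.
resolve_amplitudes <- function(cfg) {
  am <- cfg$amplitude
  if (is.numeric(am)) {
    amp <- rep_len(am, cfg$n_rois)
  } else if (identical(am$dist, "exponential")) {
    amp <- stats::rexp(cfg$n_rois, rate = 1 / am$mean)
  } else if (identical(am$dist, "fixed")) {
    resp <- am$responder
    if (is.null(resp)) resp <- TRUE
    if (is.numeric(resp) && length(resp) == 1) {
      resp <- stats::runif(cfg$n_rois) < resp
    }
    amp <- ifelse(rep_len(resp, cfg$n_rois), am$value, 0)
  } else {
    stop("unknown amplitude model")
  }
  amp
}

resolve_onsets <- function(cfg) {
  ol <- cfg$onset_latency
  if (inherits(ol, "latency_mixture")) {
    # internal draw: RNG stream already seeded by the caller
    comp <- sample.int(length(ol$locations), cfg$n_rois, replace = TRUE,
                       prob = ol$weights)
    x <- stats::rnorm(cfg$n_rois, ol$locations[comp], ol$sigma[comp])
    while (any(x < 0)) {
      bad <- x < 0
      x[bad] <- stats::rnorm(sum(bad), ol$locations[comp[bad]],
                             ol$sigma[comp[bad]])
    }
    x
  } else {
    rep_len(ol, cfg$n_rois)
  }
}

# Noiseless per-ROI dF/F signal over the trial schedule. Each trial is an
# independent epoch; the kernel is peak-normalized so `amp` is the peak dF/F.
signal_matrix <- function(cfg, amp, onset_l, time_ms, onsets) {
  pk <- kernel_peak_factor(cfg$tau_r, cfg$tau_d)
  epoch <- cfg$baseline_ms + cfg$window_ms
  sig <- matrix(0, cfg$n_rois, length(time_ms))
  epoch_id <- pmin(floor(time_ms / epoch) + 1, length(onsets))
  for (r in seq_len(cfg$n_rois)) {
    if (amp[r] == 0) next
    d <- time_ms - onsets[epoch_id]
    sig[r, ] <- transient_kernel(d, amp[r] / pk, cfg$tau_r, cfg$tau_d,
                                 onset = onset_l[r])
  }
  sig
}

#' Simulate ROI fluorescence traces with ground truth
#'
#' `F(t) = f0 * (1 + signal(t)) + N(0, (noise_sd_frac * f0)^2)`, with the
#' noiseless signal a peak-normalized transient kernel locked to each
#' trial's stimulus onset. The drawn amplitude is the true peak dF/F.
#'
#' @param cfg a [scene_config()].
#' @return list: `traces` (a [trace_matrix()] of raw F), `trials`
#'   (data.frame `trial_id, onset_ms`), `truth` (list with per-ROI
#'   data.frame `roi_id, responder, amplitude, onset_latency_ms`, the
#'   noiseless signal matrix, and the config). The truth responder flag is
#'   `amplitude >= 0.10`, the detection threshold the amplitude models are
#'   calibrated against.
#' @export
simulate_traces <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(cfg$seed)
  epoch <- cfg$baseline_ms + cfg$window_ms
  total <- epoch * cfg$n_trials
  time_ms <- seq(0, total - cfg$frame_period / 2, by = cfg$frame_period)
  onsets <- cfg$baseline_ms + (seq_len(cfg$n_trials) - 1) * epoch
  amp <- resolve_amplitudes(cfg)
  onset_l <- resolve_onsets(cfg)
  sig <- signal_matrix(cfg, amp, onset_l, time_ms, onsets)
  noise <- matrix(stats::rnorm(length(sig), 0, cfg$noise_sd_frac * cfg$f0),
                  nrow(sig), ncol(sig))
  vals <- cfg$f0 * (1 + sig) + noise
  vals[vals < 0] <- 0
  roi_id <- sprintf("roi_%03d", seq_len(cfg$n_rois))
  rownames(vals) <- roi_id
  list(
    traces = trace_matrix(vals, time_ms),
    trials = data.frame(trial_id = seq_len(cfg$n_trials), onset_ms = onsets),
    truth = list(
      rois = data.frame(roi_id = roi_id, responder = amp >= 0.10,
                        amplitude = amp, onset_latency_ms = onset_l),
      noiseless_signal = sig,
      config = cfg
    )
  )
}

#' Simulate a fluorescence movie with somata, motion, and ground truth
#'
#' Gaussian soma blobs modulated by their trial-locked transient traces are
#' rendered on a constant background, shifted rigidly frame by frame along
#' the motion path (exposed borders filled at background level), and
#' corrupted with additive Gaussian noise. ROI masks are the blob supports
#' (pixels within `soma_radius` of each center). The emitted truth includes
#' the per-frame shift path and each ROI's noiseless mask-mean trace, so
#' registration and extraction can be validated exactly in the noiseless,
#' motionless case.
#'
#' @inheritParams simulate_traces
#' @return list: `movie` (a [ca_movie()]), `rois` (a [roi_set()]), `truth`
#'   (adds `shifts` and `noiseless_roi_traces` to the [simulate_traces()]
#'   truth; `overlap_warning` flags somata closer than 2 radii).
#' @export
simulate_movie <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  sim <- simulate_traces(cfg)  # seeds the stream; reuse its signal + truth
  sig <- sim$truth$noiseless_signal
  nt <- length(sim$traces$time_ms)
  d <- cfg$grid_shape
  margin <- cfg$soma_radius + cfg$max_shift + 1
  if (2 * margin >= min(d)) stop("grid too small for soma placement")
  centers <- matrix(NA_real_, cfg$n_rois, 2)
  for (r in seq_len(cfg$n_rois)) {
    for (try in 1:200) {
      cand <- c(stats::runif(1, margin, d[1] - margin),
                stats::runif(1, margin, d[2] - margin))
      if (r == 1 || all(sqrt(rowSums(sweep(centers[seq_len(r - 1), ,
                                                   drop = FALSE],
                                           2, cand)^2)) >
                        2.5 * cfg$soma_radius) || try == 200) {
        centers[r, ] <- cand
        break
      }
    }
  }
  dists <- as.matrix(stats::dist(centers))
  overlap_warning <- any(dists[upper.tri(dists)] < 2 * cfg$soma_radius)
  if (overlap_warning) warning("somata overlap beyond threshold")

  # static soma weight images and ROI masks
  rowg <- matrix(seq_len(d[1]), d[1], d[2])
  colg <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  weights <- vector("list", cfg$n_rois)
  masks <- vector("list", cfg$n_rois)
  for (r in seq_len(cfg$n_rois)) {
    dist2 <- (rowg - centers[r, 1])^2 + (colg - centers[r, 2])^2
    w <- exp(-dist2 / (2 * (cfg$soma_radius / 2)^2))
    w[dist2 > (2 * cfg$soma_radius)^2] <- 0
    weights[[r]] <- w
    masks[[r]] <- which(dist2 <= cfg$soma_radius^2, arr.ind = TRUE)
  }

  path <- cfg$motion_path
  if (is.null(path)) {
    path <- matrix(0L, nt, 2)
  } else if (identical(path, "random_walk")) {
    steps <- matrix(sample(c(-1L, 0L, 0L, 1L), 2 * nt, replace = TRUE), nt, 2)
    path <- apply(steps, 2, cumsum)
    path <- pmax(pmin(path, cfg$max_shift), -cfg$max_shift)
  } else {
    path <- as.matrix(path)
    stopifnot(nrow(path) == nt, ncol(path) == 2)
  }
  colnames(path) <- c("dx", "dy")

  static <- Reduce(`+`, lapply(weights, function(w) cfg$f0 * w))
  frames <- array(0, dim = c(d[1], d[2], nt))
  noiseless_roi <- matrix(0, cfg$n_rois, nt)
  mask_idx <- lapply(masks, function(m) (m[, 2] - 1L) * d[1] + m[, 1])
  for (k in seq_len(nt)) {
    scene <- cfg$background + static
    for (r in seq_len(cfg$n_rois)) {
      if (sig[r, k] != 0) {
        scene <- scene + cfg$f0 * weights[[r]] * sig[r, k]
      }
    }
    for (r in seq_len(cfg$n_rois)) {
      noiseless_roi[r, k] <- mean(scene[mask_idx[[r]]])
    }
    if (path[k, 1] != 0 || path[k, 2] != 0) {
      scene <- translate_frame(scene, path[k, 1], path[k, 2])
      scene[is.na(scene)] <- cfg$background
    }
    if (cfg$noise_sd_frac > 0) {
      scene <- scene + stats::rnorm(length(scene), 0,
                                    cfg$noise_sd_frac * cfg$f0)
      scene[scene < 0] <- 0
    }
    frames[, , k] <- scene
  }
  names(masks) <- sim$truth$rois$roi_id
  truth <- sim$truth
  truth$shifts <- data.frame(frame = seq_len(nt), dx = path[, "dx"],
                             dy = path[, "dy"])
  truth$noiseless_roi_traces <- noiseless_roi
  truth$centers <- centers
  truth$overlap_warning <- overlap_warning
  list(
    movie = ca_movie(frames, frame_period = cfg$frame_period),
    rois = roi_set(masks, layer_tag = "synthetic"),
    truth = truth
  )
}

#' Simulate a pre/post activation plateau trace
#'
#' Emulates the axon-terminal chemogenetic readout: a pre-activation
#' baseline at `f0` followed by a sustained plateau at `fold * f0`, with
#' additive Gaussian noise of SD `noise_sd_frac * f0`. [fold_change()] on
#' the two windows recovers `fold` up to the sampling error of the window
#' means.
#'
#' @param f0 baseline level.
#' @param fold true post/pre ratio (default 1.4).
#' @param n_pre,n_post samples per window.
#' @param noise_sd_frac Gaussian noise SD as a fraction of `f0`.
#' @param sample_period_ms sampling interval.
#' @param seed RNG seed.
#' @return list: `trace`, `time_ms`, `pre_window`, `post_window`, `truth`.
#' @export
simulate_plateau_trace <- function(f0 = 100, fold = 1.4, n_pre = 200,
                                   n_post = 200, noise_sd_frac = 0.02,
                                   sample_period_ms = 1, seed = 1) {
  set.seed(seed)
  n <- n_pre + n_post
  level <- c(rep(f0, n_pre), rep(fold * f0, n_post))
  trace <- level + stats::rnorm(n, 0, noise_sd_frac * f0)
  trace[trace < 0] <- 0
  time_ms <- (seq_len(n) - 1) * sample_period_ms
  list(trace = trace, time_ms = time_ms,
       pre_window = c(0, n_pre * sample_period_ms),
       post_window = c(n_pre * sample_period_ms, n * sample_period_ms),
       truth = list(fold = fold, f0 = f0, seed = seed))
}

#' Simulate behavioral assay tables
#'
#' von Frey responses are Binomial(n_trials) draws from a logistic
#' psychometric curve in log force, `p(f) = plogis(slope * (log f - log
#' f*))`; `slope = Inf` gives a step at the true threshold `f*`. Escape
#' latencies are drawn from a point-mass or gamma distribution and converted
#' to first-escape frames at the camera rate.
#'
#' @param n_animals animals per table.
#' @param threshold_g true mechanical threshold f*, g (scalar or per
#'   animal).
#' @param slope logistic slope (default 8; `Inf` = deterministic step).
#' @param forces ascending filament series, g.
#' @param n_trials applications per filament.
#' @param escape_latency list: `list(dist = "point", value = 0.5)` or
#'   `list(dist = "gamma", shape, rate)` (seconds).
#' @param n_escape_trials foot-shock trials per animal.
#' @param fps camera frame rate.
#' @param seed RNG seed.
#' @return list: `von_frey` (animal, force_g, responses), `escape`
#'   (animal, trial, first_escape_frame), `truth`.
#' @export
simulate_behavior <- function(n_animals = 10, threshold_g = 0.6, slope = 8,
                              forces = c(0.04, 0.07, 0.16, 0.4, 0.6,
                                         1.0, 1.4, 2.0),
                              n_trials = 5,
                              escape_latency = list(dist = "point",
                                                    value = 0.5),
                              n_escape_trials = 3, fps = 30, seed = 1) {
  set.seed(seed)
  thr <- rep_len(threshold_g, n_animals)
  vf <- do.call(rbind, lapply(seq_len(n_animals), function(a) {
    p <- if (is.infinite(slope)) {
      as.numeric(forces >= thr[a])
    } else {
      stats::plogis(slope * (log(forces) - log(thr[a])))
    }
    data.frame(animal = a, force_g = forces,
               responses = stats::rbinom(length(forces), n_trials, p))
  }))
  lat <- switch(escape_latency$dist,
    point = rep(escape_latency$value, n_animals * n_escape_trials),
    gamma = stats::rgamma(n_animals * n_escape_trials,
                          shape = escape_latency$shape,
                          rate = escape_latency$rate),
    stop("unknown escape latency distribution")
  )
  esc <- data.frame(
    animal = rep(seq_len(n_animals), each = n_escape_trials),
    trial = rep(seq_len(n_escape_trials), n_animals),
    first_escape_frame = as.integer(round(lat * fps))
  )
  list(von_frey = vf, escape = esc,
       truth = list(threshold_g = thr, escape_latency = escape_latency,
                    slope = slope, seed = seed))
}

#' Serialize generator ground truth as JSON
#'
#' Writes the truth list (minus the bulky noiseless matrices, which are
#' reproducible from the config) losslessly beside the generated dataset.
#'
#' @param truth truth list from a generator.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  slim <- truth[setdiff(names(truth),
                        c("noiseless_signal", "noiseless_roi_traces"))]
  if (inherits(slim$config, "scene_config")) {
    slim$config <- unclass(slim$config)
    if (inherits(slim$config$onset_latency, "latency_mixture")) {
      slim$config$onset_latency <- unclass(slim$config$onset_latency)
    }
  }
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
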
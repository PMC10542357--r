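# Independent oracles and fixture builders, kept deliberately naive so they
# check the implementation rather than mirror it.

# Random textured image (seeded); enough structure for unambiguous NCC peaks.
random_image <- function(nrow = 24, ncol = 24, seed = 1) {
  set.seed(seed)
  matrix(runif(nrow * ncol, 0, 100), nrow, ncol)
}

# Brute-force translation oracle: plain double loop, Pearson correlation on
# the overlap, candidates visited in preference order (norm, then dx, dy).
oracle_translation <- function(frame, reference, max_shift) {
  best <- NULL
  best_score <- -Inf
  cand <- expand.grid(dx = -max_shift:max_shift, dy = -max_shift:max_shift)
  cand <- cand[order(cand$dx^2 + cand$dy^2, cand$dx, cand$dy), ]
  h <- nrow(reference); w <- ncol(reference)
  for (i in seq_len(nrow(cand))) {
    dx <- cand$dx[i]; dy <- cand$dy[i]
    a <- c(); b <- c()
    for (r in 1:h) for (cc in 1:w) {
      rs <- r - dy; cs <- cc - dx
      if (rs >= 1 && rs <= h && cs >= 1 && cs <= w) {
        a <- c(a, frame[rs, cs]); b <- c(b, reference[r, cc])
      }
    }
    if (length(a) < 3 || sd(a) == 0 || sd(b) == 0) next
    s <- cor(a, b)
    if (s > best_score + 1e-12) {
      best_score <- s
      best <- c(dx = dx, dy = dy)
    }
  }
  best
}

# Brute-force two-sample KS statistic: evaluate both ECDFs at every pooled
# point by counting.
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  d <- 0
  for (x in pts) {
    d <- max(d, abs(mean(a <= x) - mean(b <= x)))
  }
  d
}

# Exact threshold-crossing time of the saturating-rise kernel
# 1 - exp(-(t - onset)/tau_r) = thr.
oracle_crossing_time <- function(onset, tau_r, thr) {
  onset - tau_r * log(1 - thr)
}

# Jittered movie builder: scene shifted per frame (content moved by
# path[k, ] = c(dx, dy)), exposed borders refilled with the background so
# frames stay NA-free, as an acquisition would.
jittered_movie <- function(scene, path, background = 0,
                           frame_period = 33.3) {
  nt <- nrow(path)
  fr <- array(background, dim = c(dim(scene), nt))
  for (k in seq_len(nt)) {
    shifted <- evokedca::translate_frame(scene, path[k, 1], path[k, 2])
    shifted[is.na(shifted)] <- background
    fr[, , k] <- shifted
  }
  evokedca::ca_movie(fr, frame_period = frame_period)
}
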
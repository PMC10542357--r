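#' Rigid x-y motion correction
#'
#' Awake-imaging movies drift relative to the objective. Each frame is
#' realigned to a reference image (the average of the stable frames) by the
#' integer x-y translation that maximizes the zero-normalized
#' cross-correlation (NCC) over the overlap region, searched exhaustively in
#' `[-max_shift, max_shift]^2`. Translation only: no rotation, no subpixel
#' interpolation, so intensities are never resampled.
#'
#' @name registration
NULL

# Candidate shifts ordered by preference: smallest ||(dx, dy)||, then
# lexicographic (dx, dy). Ties in NCC resolve to the earliest candidate.
shift_candidates <- function(max_shift) {
  g <- expand.grid(dy = -max_shift:max_shift, dx = -max_shift:max_shift)
  g <- g[order(g$dx^2 + g$dy^2, g$dx, g$dy), , drop = FALSE]
  g
}

# Zero-normalized cross-correlation between frame translated by (dx, dy) and
# the reference, over the overlap; complete (non-NA) pairs only.
ncc_at_shift <- function(frame, reference, dx, dy) {
  d <- dim(reference)
  rows <- max(1L, 1L + dy):min(d[1], d[1] + dy)
  cols <- max(1L, 1L + dx):min(d[2], d[2] + dx)
  if (length(rows) < 2L || length(cols) < 2L) return(NA_real_)
  a <- as.vector(frame[rows - dy, cols - dx, drop = FALSE])
  b <- as.vector(reference[rows, cols, drop = FALSE])
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Estimate the rigid translation aligning a frame to a reference
#'
#' Finds the integer shift `(dx, dy)` — the correction applied to the frame,
#' with x along columns and y along rows — that maximizes the zero-normalized
#' cross-correlation with the reference over the overlap region. The search
#' is exhaustive over the `(2 * max_shift + 1)^2` grid; NCC ties are broken
#' by the smallest shift norm, then lexicographically by `(dx, dy)`.
#'
#' Because the correlation is zero-normalized, the estimate is invariant to
#' positive affine rescaling of frame intensities. A constant (zero-variance)
#' frame or reference has no defined NCC: the shift is reported as `(0, 0)`
#' with `ncc_score = NA`.
#'
#' @param frame 2-D numeric matrix.
#' @param reference 2-D numeric matrix of the same shape (see
#'   [compute_reference()]).
#' @param max_shift search radius in pixels (default 20).
#' @return list with `dx`, `dy` (integers) and `ncc_score` (peak NCC in
#'   `[-1, 1]`, or `NA` when undefined).
#' @export
estimate_translation <- function(frame, reference, max_shift = 20L) {
  stopifnot(is.matrix(frame), is.matrix(reference))
  if (!identical(dim(frame), dim(reference))) {
    stop("frame and reference must share one shape")
  }
  if (max_shift < 0) stop("max_shift must be >= 0")
  max_shift <- as.integer(max_shift)
  cand <- shift_candidates(max_shift)
  best <- list(dx = 0L, dy = 0L, ncc_score = NA_real_)
  best_score <- -Inf
  any_defined <- FALSE
  for (i in seq_len(nrow(cand))) {
    s <- ncc_at_shift(frame, reference, cand$dx[i], cand$dy[i])
    if (is.na(s)) next
    any_defined <- TRUE
    if (s > best_score + 1e-12) {
      best_score <- s
      best <- list(dx = as.integer(cand$dx[i]), dy = as.integer(cand$dy[i]),
                   ncc_score = s)
    }
  }
  if (!any_defined) return(list(dx = 0L, dy = 0L, ncc_score = NA_real_))
  best
}

#' Translate a frame by an integer shift
#'
#' Content moves by `dx` columns and `dy` rows; pixels exposed at the
#' borders are marked invalid (`NA`) rather than zero-filled, so ROI means
#' are never contaminated by padding.
#'
#' @param frame 2-D numeric matrix.
#' @param dx,dy integer shift in pixels (x = columns, y = rows).
#' @return translated matrix of the same shape.
#' @export
translate_frame <- function(frame, dx, dy) {
  d <- dim(frame)
  out <- matrix(NA_real_, d[1], d[2])
  rows <- max(1L, 1L + dy):min(d[1], d[1] + dy)
  cols <- max(1L, 1L + dx):min(d[2], d[2] + dx)
  if (length(rows) >= 1L && length(cols) >= 1L && rows[1] <= rows[length(rows)]) {
    out[rows, cols] <- frame[rows - dy, cols - dx, drop = FALSE]
  }
  out
}

#' Build the stable-frame reference image
#'
#' Two-pass rule: pass 1 averages all frames and scores every frame by its
#' zero-shift NCC against that mean; pass 2 averages the frames whose score
#' is at or above the `(1 - stability_quantile)` quantile — i.e. the top
#' `stability_quantile` fraction of frames, the "stable" ones. With the
#' default 0.8, the 20% of frames least correlated with the session mean
#' (typically those caught mid-motion) are excluded.
#'
#' @param movie a [ca_movie()].
#' @param stability_quantile fraction of frames retained, in `(0, 1]`.
#' @return matrix with attributes `n_frames_used` (frames averaged) and
#'   `single_frame` (TRUE when the movie had only one frame).
#' @export
compute_reference <- function(movie, stability_quantile = 0.8) {
  stopifnot(inherits(movie, "ca_movie"))
  if (stability_quantile <= 0 || stability_quantile > 1) {
    stop("stability_quantile must be in (0, 1]")
  }
  fr <- movie$frames
  if (any(is.nan(fr)) || any(is.infinite(fr))) {
    stop("compute_reference requires finite pixel values")
  }
  nf <- dim(fr)[3]
  if (nf == 1L) {
    warning("single-frame movie: reference is that frame")
    ref <- fr[, , 1]
    attr(ref, "n_frames_used") <- 1L
    attr(ref, "single_frame") <- TRUE
    return(ref)
  }
  mean_all <- apply(fr, c(1, 2), mean, na.rm = TRUE)
  mean_all[is.nan(mean_all)] <- NA_real_
  scores <- vapply(seq_len(nf), function(k) {
    ncc_at_shift(fr[, , k], mean_all, 0L, 0L)
  }, numeric(1))
  if (all(is.na(scores))) {
    keep <- rep(TRUE, nf)  # constant movie: every frame is "stable"
  } else {
    thr <- stats::quantile(scores, probs = 1 - stability_quantile,
                           na.rm = TRUE, names = FALSE)
    keep <- !is.na(scores) & scores >= thr
  }
  ref <- apply(fr[, , keep, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
  ref[is.nan(ref)] <- NA_real_
  attr(ref, "n_frames_used") <- sum(keep)
  attr(ref, "single_frame") <- FALSE
  ref
}

#' Register a movie by per-frame rigid translation
#'
#' Estimates and applies the NCC-optimal integer shift for every frame
#' against the stable-frame reference. Exposed border pixels become `NA`
#' (invalid). Frames whose peak NCC falls below `score_floor` are flagged
#' low-confidence but kept.
#'
#' @inheritParams compute_reference
#' @param max_shift search radius in pixels.
#' @param score_floor NCC below which a frame is flagged (default 0.3).
#' @param reference optional precomputed reference matrix; computed from the
#'   movie when `NULL`.
#' @return list with `movie` (registered [ca_movie()]), `shifts` (data.frame
#'   `frame, dx, dy, ncc_score, low_confidence`) and `reference`.
#' @export
register_movie <- function(movie, max_shift = 20L, stability_quantile = 0.8,
                           score_floor = 0.3, reference = NULL) {
  stopifnot(inherits(movie, "ca_movie"))
  if (is.null(reference)) {
    reference <- compute_reference(movie, stability_quantile)
  }
  nf <- n_frames(movie)
  out <- movie$frames
  shifts <- data.frame(frame = seq_len(nf), dx = 0L, dy = 0L,
                       ncc_score = NA_real_, low_confidence = FALSE)
  for (k in seq_len(nf)) {
    est <- estimate_translation(movie$frames[, , k], reference, max_shift)
    shifts$dx[k] <- est$dx
    shifts$dy[k] <- est$dy
    shifts$ncc_score[k] <- est$ncc_score
    shifts$low_confidence[k] <- is.na(est$ncc_score) ||
      est$ncc_score < score_floor
    if (est$dx != 0L || est$dy != 0L) {
      out[, , k] <- translate_frame(movie$frames[, , k], est$dx, est$dy)
    }
  }
  reg <- movie
  reg$frames <- out
  list(movie = reg, shifts = shifts, reference = reference)
}

#' Write / read a shift table as CSV
#'
#' Columns `frame, dx, dy, ncc_score, low_confidence`.
#'
#' @param shifts data.frame as returned by [register_movie()].
#' @param path CSV file.
#' @return `path` invisibly / the data.frame.
#' @export
write_shifts_csv <- function(shifts, path) {
  utils::write.csv(shifts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shifts_csv
#' @export
read_shifts_csv <- function(path) {
  utils::read.csv(path)
}
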
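#' ROI trace matrix
#'
#' ROI-by-time fluorescence on one uniform time base. Covers both temporal
#' modes of the acquisition: frame scan (33.3 ms/frame) and line scan
#' (ms-scale sampling on selected cells, typically ingested from CSV). A
#' validity mask tracks samples lost to registration borders.
#'
#' @param values numeric matrix, one row per ROI.
#' @param time_ms sample times in ms; strictly increasing and uniform.
#' @param roi_id character vector of ROI ids (defaults to rownames).
#' @param valid logical matrix matching `values` (default: `!is.na(values)`).
#' @return object of class `trace_matrix`.
#' @export
trace_matrix <- function(values, time_ms, roi_id = rownames(values),
                         valid = NULL) {
  values <- as.matrix(values)
  if (is.null(roi_id)) roi_id <- paste0("roi_", seq_len(nrow(values)))
  stopifnot(length(time_ms) == ncol(values), length(roi_id) == nrow(values))
  if (anyDuplicated(roi_id)) stop("roi_id must be unique")
  dt <- diff(time_ms)
  if (length(dt) > 0) {
    if (any(dt <= 0)) stop("time base must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6 * max(dt)) {
      stop("time base must be uniform")
    }
  }
  if (is.null(valid)) valid <- !is.na(values)
  values[!valid] <- NA_real_
  rownames(values) <- roi_id
  structure(
    list(values = values, time_ms = as.numeric(time_ms), roi_id = roi_id,
         valid = valid,
         sample_period = if (length(dt)) stats::median(dt) else NA_real_),
    class = "trace_matrix"
  )
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d ROIs x %d samples, %.4g ms/sample\n",
              nrow(x$values), ncol(x$values), x$sample_period))
  invisible(x)
}

#' Extract ROI-mean fluorescence traces from a movie
#'
#' Each sample is the mean intensity over the ROI's valid (non-`NA`) pixels
#' in that frame. Samples where every ROI pixel is invalid are masked.
#'
#' @param movie a [ca_movie()] (typically registered).
#' @param rois a [roi_set()].
#' @return a [trace_matrix()] on the movie's frame-start time base.
#' @export
extract_traces <- function(movie, rois) {
  stopifnot(inherits(movie, "ca_movie"), inherits(rois, "roi_set"))
  d <- dim(movie$frames)
  nf <- d[3]
  flat <- matrix(movie$frames, nrow = d[1] * d[2], ncol = nf)
  vals <- matrix(NA_real_, length(rois$pixels), nf,
                 dimnames = list(names(rois$pixels), NULL))
  for (id in names(rois$pixels)) {
    px <- rois$pixels[[id]]
    if (any(px[, 1] > d[1]) || any(px[, 2] > d[2])) {
      stop(sprintf("ROI '%s' lies outside the %d x %d grid", id, d[1], d[2]))
    }
    idx <- (px[, 2] - 1L) * d[1] + px[, 1]
    vals[id, ] <- colMeans(flat[idx, , drop = FALSE], na.rm = TRUE)
  }
  vals[is.nan(vals)] <- NA_real_  # all-invalid pixel sets
  trace_matrix(vals, frame_times(movie))
}

#' Per-trial baseline fluorescence F0
#'
#' F0 is the mean of the valid samples in the half-open window
#' `[onset - baseline_duration, onset)` — the 10 s preceding the trial by
#' default. The onset sample itself belongs to the response epoch, never to
#' the baseline. When the recording covers less than the full window, the
#' available pre-onset samples are used and a truncation flag is set.
#'
#' @param trace numeric vector of fluorescence samples (one ROI).
#' @param time_ms sample times, ms.
#' @param onset trial onset time, ms.
#' @param baseline_duration window length, ms (default 10000).
#' @return list with `f0`, `n_samples`, and `truncated`.
#' @export
trial_baseline <- function(trace, time_ms, onset, baseline_duration = 10000) {
  stopifnot(baseline_duration > 0)
  sel <- time_ms >= onset - baseline_duration & time_ms < onset
  vals <- trace[sel]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop("no valid samples in the pre-onset baseline window")
  }
  f0 <- mean(vals)
  if (f0 <= 0) stop("baseline F0 <= 0: broken input")
  list(f0 = f0, n_samples = length(vals),
       truncated = time_ms[1] > onset - baseline_duration)
}

#' Baseline-normalized fluorescence change
#'
#' `dff(t) = (F(t) - F0) / F0`, dimensionless; `NA` samples propagate.
#' Invariant to positive multiplicative gain applied to both `F` and `F0`.
#'
#' @param trace numeric fluorescence vector.
#' @param f0 positive baseline from [trial_baseline()].
#' @return numeric dF/F vector.
#' @export
compute_dff <- function(trace, f0) {
  if (!is.numeric(f0) || length(f0) != 1L || is.na(f0) || f0 <= 0) {
    stop("F0 must be a single positive number")
  }
  (trace - f0) / f0
}

#' Per-trial dF/F in long format
#'
#' Applies [trial_baseline()] and [compute_dff()] to every ROI x trial pair.
#' The trial epoch spans the baseline window through `onset + window_ms`.
#'
#' @param traces a [trace_matrix()] of raw fluorescence.
#' @param trials data.frame with columns `trial_id` and `onset_ms`.
#' @param window_ms response-epoch length after onset, ms.
#' @param baseline_duration baseline window, ms.
#' @return data.frame `roi_id, trial_id, t_ms, dff, f0`.
#' @export
dff_by_trial <- function(traces, trials, window_ms = 2000,
                         baseline_duration = 10000) {
  stopifnot(inherits(traces, "trace_matrix"),
            all(c("trial_id", "onset_ms") %in% names(trials)))
  out <- vector("list", nrow(trials) * length(traces$roi_id))
  i <- 0L
  for (ti in seq_len(nrow(trials))) {
    onset <- trials$onset_ms[ti]
    sel <- traces$time_ms >= onset - baseline_duration &
      traces$time_ms <= onset + window_ms
    for (id in traces$roi_id) {
      f <- traces$values[id, ]
      bl <- trial_baseline(f, traces$time_ms, onset, baseline_duration)
      i <- i + 1L
      out[[i]] <- data.frame(
        roi_id = id, trial_id = trials$trial_id[ti],
        t_ms = traces$time_ms[sel],
        dff = compute_dff(f[sel], bl$f0), f0 = bl$f0
      )
    }
  }
  do.call(rbind, out)
}

#' Write / read a trace matrix as long-format CSV
#'
#' Columns `roi_id, t_ms, F, valid`. Values are written with 17 significant
#' digits so a round trip preserves doubles exactly.
#'
#' @param traces a [trace_matrix()].
#' @param path CSV file.
#' @return `path` invisibly / a [trace_matrix()].
#' @export
write_traces_csv <- function(traces, path) {
  long <- data.frame(
    roi_id = rep(traces$roi_id, times = ncol(traces$values)),
    t_ms = format(rep(traces$time_ms, each = nrow(traces$values)),
                  digits = 17, scientific = FALSE, trim = TRUE),
    F = format(as.vector(traces$values), digits = 17, trim = TRUE),
    valid = as.vector(traces$valid)
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  long <- utils::read.csv(path)
  ids <- unique(long$roi_id)
  ts <- sort(unique(long$t_ms))
  vals <- matrix(NA_real_, length(ids), length(ts),
                 dimnames = list(ids, NULL))
  valid <- matrix(FALSE, length(ids), length(ts))
  ri <- match(long$roi_id, ids)
  ci <- match(long$t_ms, ts)
  vals[cbind(ri, ci)] <- long$F
  valid[cbind(ri, ci)] <- long$valid
  trace_matrix(vals, ts, roi_id = as.character(ids), valid = valid)
}

#' Read a line-scan trace table
#'
#' Line scanning revisits selected cells at ms-scale intervals; traces enter
#' as a wide CSV with a `t_ms` column plus one column per ROI, or as the long
#' format of [write_traces_csv()]. The declared sample period is validated
#' against the time stamps.
#'
#' @param path CSV file.
#' @param sample_period_ms declared sampling interval (default 1 ms).
#' @return a [trace_matrix()].
#' @export
read_linescan_csv <- function(path, sample_period_ms = 1) {
  tab <- utils::read.csv(path)
  tm <- if (all(c("roi_id", "F") %in% names(tab))) {
    read_traces_csv(path)
  } else {
    stopifnot("t_ms" %in% names(tab))
    vals <- t(as.matrix(tab[, setdiff(names(tab), "t_ms"), drop = FALSE]))
    trace_matrix(vals, tab$t_ms)
  }
  if (abs(tm$sample_period - sample_period_ms) > 1e-6 * sample_period_ms) {
    warning(sprintf("declared sample period %g ms but time base has %g ms",
                    sample_period_ms, tm$sample_period))
  }
  tm
}
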
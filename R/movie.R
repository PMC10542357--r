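#' Fluorescence movie container
#'
#' A `ca_movie` holds a 3-D fluorescence stack as an array of dimension
#' `c(rows, cols, frames)` together with its acquisition clock: the frame
#' period in milliseconds and the time of the first frame. Pixel intensities
#' must be non-negative; `NA` marks pixels invalidated by registration
#' (exposed borders) and is excluded from all downstream ROI averages.
#'
#' @param frames numeric array `rows x cols x frames`, or a matrix for a
#'   single-frame movie. Finite non-negative values or `NA`.
#' @param frame_period milliseconds per frame (default 33.3, the typical
#'   512 x 512 resonant-scan rate).
#' @param origin_time acquisition time of the first frame, ms.
#' @return an object of class `ca_movie`.
#' @export
ca_movie <- function(frames, frame_period = 33.3, origin_time = 0) {
  if (is.matrix(frames)) {
    frames <- array(frames, dim = c(dim(frames), 1L))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (!is.numeric(frame_period) || length(frame_period) != 1L ||
      !is.finite(frame_period) || frame_period <= 0) {
    stop("frame_period must be a single positive number (ms)")
  }
  bad <- is.nan(frames) | is.infinite(frames) | (!is.na(frames) & frames < 0)
  if (any(bad)) {
    stop("movie intensities must be finite and >= 0 (NA marks invalid pixels)")
  }
  structure(
    list(frames = frames, frame_period = frame_period,
         origin_time = origin_time),
    class = "ca_movie"
  )
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ca_movie> %d frames of %d x %d px, %.4g ms/frame, t0 = %g ms\n",
              d[3], d[1], d[2], x$frame_period, x$origin_time))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie a [ca_movie()].
#' @return integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[3]

#' Frame start times
#'
#' Each sample is stamped with its frame *start* time,
#' `origin_time + (k - 1) * frame_period`, matching stimulus marks on the
#' acquisition clock.
#'
#' @param movie a [ca_movie()].
#' @return numeric vector of times in ms, one per frame.
#' @export
frame_times <- function(movie) {
  movie$origin_time + (seq_len(n_frames(movie)) - 1) * movie$frame_period
}

#' Read a multi-page TIFF stack as a movie
#'
#' Pages are read in file order as frames, with raw integer sample values
#' preserved (no rescaling to `[0, 1]`).
#'
#' @param path TIFF file.
#' @inheritParams ca_movie
#' @return a [ca_movie()].
#' @export
read_movie_tiff <- function(path, frame_period = 33.3, origin_time = 0) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all TIFF pages must share one shape")
  }
  frames <- array(unlist(pages, use.names = FALSE),
                  dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]]
  ca_movie(frames, frame_period = frame_period, origin_time = origin_time)
}

#' Write a movie as a 16-bit multi-page TIFF
#'
#' Intensities are stored as 16-bit unsigned samples, so values must lie in
#' `[0, 65535]`; non-integer values are rounded on write. Invalid (`NA`)
#' pixels are stored as 0 — keep the shift table alongside if validity must
#' be reconstructed.
#'
#' @param movie a [ca_movie()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  mx <- max(movie$frames, na.rm = TRUE)
  if (mx > 65535) stop("intensities exceed the 16-bit range")
  pages <- lapply(seq_len(n_frames(movie)), function(k) {
    fr <- movie$frames[, , k]
    fr[is.na(fr)] <- 0
    fr / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}
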
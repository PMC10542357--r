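#' ROI sets
#'
#' Cell-body regions of interest are stored as explicit pixel sets (1-based
#' `(row, col)` pairs) tagged with a population label such as `"layer5_SCRN"`
#' or `"layer4"`. ROIs come from a label image (each cell one integer label)
#' or from polygon outlines rasterized by pixel-center inclusion.
#'
#' @param pixels named list; each element a 2-column integer matrix of
#'   `(row, col)` pixel coordinates.
#' @param layer_tag population label applied to every ROI.
#' @return object of class `roi_set`: list with `pixels` and `layer_tag`.
#' @export
roi_set <- function(pixels, layer_tag = "population") {
  stopifnot(is.list(pixels), length(pixels) > 0)
  ids <- names(pixels)
  if (is.null(ids) || anyDuplicated(ids) || any(ids == "")) {
    stop("ROI ids must be unique, non-empty names")
  }
  for (id in ids) {
    px <- pixels[[id]]
    if (!is.matrix(px) || ncol(px) != 2L || nrow(px) == 0L) {
      stop(sprintf("ROI '%s' must be a non-empty (row, col) matrix", id))
    }
    if (any(px < 1) || any(px != round(px))) {
      stop(sprintf("ROI '%s' has non-positive or non-integer pixels", id))
    }
    storage.mode(pixels[[id]]) <- "integer"
    colnames(pixels[[id]]) <- c("row", "col")
  }
  structure(list(pixels = pixels, layer_tag = layer_tag), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs, tag '%s'\n", length(x$pixels), x$layer_tag))
  invisible(x)
}

#' ROIs from a label image
#'
#' Every distinct non-zero label becomes one ROI named `roi_<label>`.
#'
#' @param labels integer matrix (0 = background) or path handled by
#'   [roi_from_label_tiff()].
#' @inheritParams roi_set
#' @return a [roi_set()].
#' @export
roi_from_labels <- function(labels, layer_tag = "population") {
  stopifnot(is.matrix(labels))
  labs <- sort(unique(labels[labels != 0]))
  if (length(labs) == 0) stop("label image contains no ROI labels")
  px <- lapply(labs, function(l) which(labels == l, arr.ind = TRUE))
  names(px) <- paste0("roi_", labs)
  roi_set(px, layer_tag)
}

#' @rdname roi_from_labels
#' @param path 16-bit label TIFF.
#' @export
roi_from_label_tiff <- function(path, layer_tag = "population") {
  labels <- tiff::readTIFF(path, as.is = TRUE)
  if (is.list(labels)) labels <- labels[[1]]
  roi_from_labels(matrix(as.integer(round(labels)), nrow(labels)), layer_tag)
}

# Even-odd (ray casting) point-in-polygon test for pixel centers.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' ROIs from polygon outlines (JSON)
#'
#' The JSON holds a list of objects `{"roi_id": ..., "x": [...], "y": [...]}`
#' with vertex coordinates in pixel units (x = column, y = row, 1-based).
#' Each polygon is rasterized by center inclusion: a pixel belongs to the ROI
#' iff its integer center lies inside the polygon (even-odd rule).
#'
#' @param path JSON file, or an already-parsed list of polygons.
#' @param shape `c(rows, cols)` of the movie grid, bounding rasterization.
#' @inheritParams roi_set
#' @return a [roi_set()].
#' @export
roi_from_polygons_json <- function(path, shape, layer_tag = "population") {
  polys <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    path
  }
  px <- lapply(polys, function(p) {
    vx <- as.numeric(unlist(p$x)); vy <- as.numeric(unlist(p$y))
    rlo <- max(1L, floor(min(vy))); rhi <- min(shape[1], ceiling(max(vy)))
    clo <- max(1L, floor(min(vx))); chi <- min(shape[2], ceiling(max(vx)))
    g <- expand.grid(row = rlo:rhi, col = clo:chi)
    inside <- point_in_polygon(g$col, g$row, vx, vy)
    as.matrix(g[inside, c("row", "col"), drop = FALSE])
  })
  names(px) <- vapply(polys, function(p) as.character(p$roi_id), character(1))
  roi_set(px, layer_tag)
}
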
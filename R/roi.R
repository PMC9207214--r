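#' Define a region of interest
#'
#' ROIs mirror the two tracing styles used when quantifying fluorescence:
#' a closed polygon (e.g. around a soma) or a polyline of given width traced
#' along a cell projection. Coordinates are 0-based pixel-center coordinates
#' in `(row, col)` order, row-major, matching the raster returned by
#' [rasterize_roi()]. A pixel belongs to a polygon ROI if its center is
#' inside the polygon under the even-odd rule, and to a polyline ROI if its
#' center lies within `line_width / 2` of the traced path (inclusive). No
#' sub-pixel interpolation is performed, so masks are bit-reproducible.
#'
#' @param roi_id Identifier.
#' @param kind `"polygon"` or `"polyline"`.
#' @param vertices Numeric matrix with columns `(row, col)`; at least 3 rows
#'   for a polygon, 2 for a polyline.
#' @param line_width Width in pixels for polyline ROIs (>= 1).
#' @param background Optional polygon vertex matrix delimiting a background
#'   region used by [measure_integrated_density()] for normalization.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(roi_id, kind = c("polygon", "polyline"), vertices,
                     line_width = 1, background = NULL) {
  kind <- match.arg(kind)
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L) {
    abort("`vertices` must be a numeric matrix with (row, col) columns")
  }
  min_v <- if (kind == "polygon") 3L else 2L
  if (nrow(vertices) < min_v) {
    abort(sprintf("a %s needs at least %d vertices", kind, min_v))
  }
  check_number(line_width, "line_width", lower = 1)
  if (!is.null(background)) {
    background <- as.matrix(background)
    if (!is.numeric(background) || ncol(background) != 2L || nrow(background) < 3L) {
      abort("`background` must be a polygon vertex matrix with >= 3 rows")
    }
  }
  structure(list(roi_id = as.character(roi_id), kind = kind,
                 vertices = unname(vertices), line_width = line_width,
                 background = if (is.null(background)) NULL else unname(background)),
            class = "roi_spec")
}

#' Rasterize an ROI to a boolean pixel mask
#'
#' @param roi An [roi_spec()].
#' @param rows,cols Frame dimensions in pixels.
#' @return Logical `rows x cols` matrix; `TRUE` marks pixels in the ROI.
#'   Errors if the ROI covers no pixel of the frame.
#' @export
rasterize_roi <- function(roi, rows, cols) {
  stopifnot(inherits(roi, "roi_spec"))
  check_number(rows, "rows", lower = 1, integerish = TRUE)
  check_number(cols, "cols", lower = 1, integerish = TRUE)
  mask <- if (roi$kind == "polygon") {
    polygon_mask(roi$vertices, rows, cols)
  } else {
    polyline_mask(roi$vertices, roi$line_width, rows, cols)
  }
  if (!any(mask)) abort("ROI lies entirely outside the frame")
  mask
}

# Even-odd-rule polygon fill over 0-based pixel centers. Vectorized
# ray-crossing test: a pixel is inside if a ray to the left crosses the
# polygon boundary an odd number of times.
polygon_mask <- function(vertices, rows, cols) {
  py <- rep(0:(rows - 1), times = cols)   # row coordinate
  px <- rep(0:(cols - 1), each = rows)    # col coordinate
  vy <- vertices[, 1]
  vx <- vertices[, 2]
  nv <- length(vy)
  inside <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nrow = rows, ncol = cols)
}

# Pixels whose center is within width/2 (inclusive) of any polyline segment.
polyline_mask <- function(vertices, line_width, rows, cols) {
  py <- rep(0:(rows - 1), times = cols)
  px <- rep(0:(cols - 1), each = rows)
  half <- line_width / 2
  near <- rep(FALSE, length(px))
  for (i in seq_len(nrow(vertices) - 1L)) {
    a <- vertices[i, ]
    b <- vertices[i + 1L, ]
    d <- point_segment_distance(py, px, a[1], a[2], b[1], b[2])
    near <- near | (d <= half)
  }
  matrix(near, nrow = rows, ncol = cols)
}

point_segment_distance <- function(py, px, ay, ax, by, bx) {
  vy <- by - ay
  vx <- bx - ax
  len2 <- vy^2 + vx^2
  if (len2 == 0) {
    return(sqrt((py - ay)^2 + (px - ax)^2))
  }
  tt <- ((py - ay) * vy + (px - ax) * vx) / len2
  tt <- pmin(1, pmax(0, tt))
  sqrt((py - (ay + tt * vy))^2 + (px - (ax + tt * vx))^2)
}

#' Measure ROI integrated density over an image stack
#'
#' Per frame, the raw integrated density is the sum of pixel intensities in
#' the rasterized ROI mask. If the ROI carries a background polygon, each
#' frame is normalized against the mean background pixel intensity of that
#' same frame, either by subtraction (default; `raw - mean_bg * roi_area`,
#' which keeps integrated-density units and maps a frame identical to its
#' background to 0) or by division (`raw / mean_bg`).
#'
#' @param stack An [image_stack()].
#' @param roi An [roi_spec()].
#' @param normalization `"subtract"` (default) or `"divide"`; ignored when
#'   the ROI has no background region.
#' @return A [fluorescence_trace()] with `cell_id = roi$roi_id`, one value
#'   per frame, timed by the stack's `frame_times`.
#' @export
measure_integrated_density <- function(stack, roi,
                                       normalization = c("subtract", "divide")) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "roi_spec"))
  normalization <- match.arg(normalization)
  dims <- dim(stack$pixels)
  mask <- rasterize_roi(roi, dims[2], dims[3])
  bg_mask <- NULL
  if (!is.null(roi$background)) {
    bg_mask <- polygon_mask(roi$background, dims[2], dims[3])
    if (!any(bg_mask)) abort("background ROI covers no pixel of the frame")
  }
  area <- sum(mask)
  vals <- vapply(seq_len(dims[1]), function(f) {
    frame <- stack$pixels[f, , ]
    raw <- sum(frame[mask])
    if (is.null(bg_mask)) return(raw)
    mean_bg <- mean(frame[bg_mask])
    if (normalization == "subtract") raw - mean_bg * area else raw / mean_bg
  }, numeric(1))
  fluorescence_trace(roi$roi_id, stack$frame_times, vals)
}

#' Read and write ROI definitions as JSON
#'
#' The on-disk schema is a JSON array of objects
#' `{roi_id, kind, vertices: [[r, c], ...], line_width,
#' background: {vertices: [[r, c], ...]}}` with 0-based pixel coordinates.
#'
#' @param path JSON file path.
#' @return `read_roi_json()` returns a list of [roi_spec()] objects.
#' @export
read_roi_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    verts <- do.call(rbind, lapply(r$vertices, unlist))
    bg <- NULL
    if (!is.null(r$background)) {
      bg <- do.call(rbind, lapply(r$background$vertices, unlist))
    }
    roi_spec(r$roi_id, r$kind, verts,
             line_width = r$line_width %||% 1, background = bg)
  })
}

#' @rdname read_roi_json
#' @param rois List of [roi_spec()] objects.
#' @export
write_roi_json <- function(rois, path) {
  stopifnot(is.list(rois))
  out <- lapply(rois, function(r) {
    stopifnot(inherits(r, "roi_spec"))
    obj <- list(roi_id = r$roi_id, kind = r$kind,
                vertices = apply(r$vertices, 1, as.list, simplify = FALSE),
                line_width = r$line_width)
    if (!is.null(r$background)) {
      obj$background <- list(
        vertices = apply(r$background, 1, as.list, simplify = FALSE))
    }
    obj
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
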
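#' Construct an image stack
#'
#' A grayscale multi-frame image as a 3-D array `frames x rows x cols` of
#' non-negative intensities with strictly increasing frame times. Z-stacks
#' are assumed already projected upstream.
#'
#' @param pixels 3-D numeric array, `frames x rows x cols`, non-negative.
#' @param frame_times Numeric vector of frame times in seconds, strictly
#'   increasing; defaults to `0, 1, 2, ...`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, frame_times = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    abort("`pixels` must be a 3-D array (frames x rows x cols)")
  }
  if (any(dim(pixels) < 1L)) abort("all stack dimensions must be >= 1")
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    abort("pixel intensities must be finite and non-negative")
  }
  n <- dim(pixels)[1]
  if (is.null(frame_times)) frame_times <- as.numeric(0:(n - 1))
  if (length(frame_times) != n) {
    abort("`frame_times` must have one entry per frame")
  }
  if (n > 1L && any(diff(frame_times) <= 0)) {
    abort("`frame_times` must be strictly increasing")
  }
  structure(list(pixels = pixels, frame_times = as.numeric(frame_times)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d frame(s) of %d x %d px\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Generate a synthetic moving-blob image stack with analytic ROI truth
#'
#' Renders a Gaussian blob moving along a given path over a constant
#' background, optionally adding Gaussian pixel noise, and returns alongside
#' the stack the noiseless per-frame ROI integrated density (the analytic
#' ground truth for [measure_integrated_density()]). With `roi = NULL` the
#' truth is the whole-frame sum.
#'
#' @param n_frames,height,width Stack dimensions.
#' @param blob_path Numeric matrix `n_frames x 2` of blob centers in 0-based
#'   `(row, col)` pixel coordinates; every center must lie inside the frame.
#' @param blob_amplitude Peak intensity added by the blob at its center.
#' @param blob_sigma Gaussian radius of the blob in pixels.
#' @param background_level Constant background intensity.
#' @param noise_sd Gaussian pixel noise sd (0 = noiseless); negative
#'   intensities after noise are clipped to 0.
#' @param roi Optional [roi_spec()] over which the truth is integrated.
#' @param frame_times Optional frame times (seconds).
#' @param seed Integer seed.
#' @return List with `stack` (an [image_stack()]) and `truth` (numeric
#'   vector of per-frame noiseless ROI integrated densities).
#' @export
generate_image_stack <- function(n_frames, height, width, blob_path,
                                 blob_amplitude = 50, blob_sigma = 1.5,
                                 background_level = 10, noise_sd = 0,
                                 roi = NULL, frame_times = NULL, seed = 1) {
  check_number(n_frames, "n_frames", lower = 1, integerish = TRUE)
  check_number(height, "height", lower = 1, integerish = TRUE)
  check_number(width, "width", lower = 1, integerish = TRUE)
  check_number(blob_amplitude, "blob_amplitude", lower = 0)
  check_number(blob_sigma, "blob_sigma")
  if (blob_sigma <= 0) abort("`blob_sigma` must be positive")
  check_number(background_level, "background_level", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed", integerish = TRUE)
  blob_path <- as.matrix(blob_path)
  if (nrow(blob_path) != n_frames || ncol(blob_path) != 2L) {
    abort("`blob_path` must be an n_frames x 2 matrix of (row, col) centers")
  }
  if (any(blob_path[, 1] < 0) || any(blob_path[, 1] > height - 1) ||
      any(blob_path[, 2] < 0) || any(blob_path[, 2] > width - 1)) {
    abort("blob centers must lie inside the frame")
  }
  rr <- matrix(rep(0:(height - 1), times = width), nrow = height)
  cc <- matrix(rep(0:(width - 1), each = height), nrow = height)
  clean <- array(0, dim = c(n_frames, height, width))
  for (f in seq_len(n_frames)) {
    blob <- blob_amplitude *
      exp(-((rr - blob_path[f, 1])^2 + (cc - blob_path[f, 2])^2) /
            (2 * blob_sigma^2))
    clean[f, , ] <- background_level + blob
  }
  mask <- if (is.null(roi)) {
    matrix(TRUE, height, width)
  } else {
    rasterize_roi(roi, height, width)
  }
  truth <- vapply(seq_len(n_frames), function(f) sum(clean[f, , ][mask]),
                  numeric(1))
  pixels <- clean
  if (noise_sd > 0) {
    pixels <- withr::with_seed(seed, {
      noisy <- clean + array(stats::rnorm(length(clean), 0, noise_sd),
                             dim = dim(clean))
      pmax(noisy, 0)
    })
  }
  list(stack = image_stack(pixels, frame_times), truth = truth)
}

#' Read and write image stacks as multi-frame grayscale TIFF
#'
#' Stacks are stored as 16-bit grayscale multi-frame TIFF. Intensities must
#' lie in `[0, 65535]`; integer intensities round-trip exactly. Frame times
#' are not stored in the TIFF and must be re-supplied on read.
#'
#' @param stack An [image_stack()].
#' @param path TIFF file path.
#' @param frame_times Frame times to attach on read (default `0, 1, ...`).
#' @return `read_stack_tiff()` returns an [image_stack()];
#'   `write_stack_tiff()` invisibly returns `path`.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (max(stack$pixels) > 65535) {
    abort("intensities exceed 65535; rescale before writing 16-bit TIFF")
  }
  frames <- lapply(seq_len(dim(stack$pixels)[1]), function(f) {
    stack$pixels[f, , ] / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, frame_times = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(fr) {
    if (length(dim(fr)) == 3L) fr <- fr[, , 1]  # collapse replicated channels
    round(fr * 65535)  # storage is 16-bit integer, so gray levels are whole
  })
  pixels <- array(0, dim = c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
  for (f in seq_along(frames)) pixels[f, , ] <- frames[[f]]
  image_stack(pixels, frame_times)
}
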
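#' Z-score an integrated-density trace
#'
#' Standardizes a trace against its own whole-trace mean and sample standard
#' deviation (divisor n - 1): `z_t = (x_t - mean(x)) / sd(x)`. This is the
#' single-Z-per-trace computation used to score GCaMP integrated densities;
#' a pre-stimulus baseline window can be used as the reference instead for
#' evoked protocols.
#'
#' A zero-variance (constant) trace cannot be standardized; it yields an
#' all-zero series carrying the attribute `degenerate = TRUE`, which the
#' event caller treats as "no events" (a flat trace is inactive).
#'
#' @param trace A [fluorescence_trace()] with at least two samples.
#' @param baseline_window Optional numeric `c(start_s, end_s)`: compute the
#'   reference mean/sd only from samples with time in `[start_s, end_s]`
#'   (at least two samples required). Default `NULL` uses the whole trace.
#' @return Numeric z-score vector, with attribute `degenerate` (logical).
#' @export
zscore_trace <- function(trace, baseline_window = NULL) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  x <- trace$intensity
  if (length(x) < 2L) abort("z-scoring needs at least two samples")
  ref <- x
  if (!is.null(baseline_window)) {
    if (!is.numeric(baseline_window) || length(baseline_window) != 2L) {
      abort("`baseline_window` must be c(start_s, end_s)")
    }
    keep <- trace$t_s >= baseline_window[1] & trace$t_s <= baseline_window[2]
    if (sum(keep) < 2L) abort("`baseline_window` must contain at least two samples")
    ref <- x[keep]
  }
  m <- mean(ref)
  s <- stats::sd(ref)
  if (s == 0) {
    z <- rep(0, length(x))
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  z <- (x - m) / s
  attr(z, "degenerate") <- FALSE
  z
}

#' Call calcium transient events from a z-score series
#'
#' Marks every sample with `z >= threshold` as transient-positive (the
#' threshold is inclusive: z exactly at the threshold scores) and groups
#' maximal runs of consecutive supra-threshold samples into one event each.
#' Runs separated by fewer than `min_gap_samples` sub-threshold samples are
#' merged into a single event; the default of 1 merges nothing, i.e. every
#' contiguous run is its own peak. A cell is "active" if it has at least one
#' event.
#'
#' @param z_series Numeric z-score vector (finite), e.g. from
#'   [zscore_trace()].
#' @param threshold Z threshold at or above which a sample is
#'   transient-positive. Default 2.
#' @param min_gap_samples Runs separated by fewer than this many
#'   sub-threshold samples are merged. Default 1 (no merging).
#' @param cell_id,animal_id,cell_class Optional identifiers copied into the
#'   result (filled automatically by [detect_calcium_events()]).
#' @return An object of class `event_call_result`: a list with `cell_id`,
#'   `animal_id`, `cell_class`, `z_series`, `events` (data frame with
#'   columns `start`, `end`, `peak_z`; 1-based inclusive sample indices),
#'   `n_peaks`, `is_active` and `epoch_counts` (`NULL` until
#'   [epoch_event_counts()] is applied).
#' @export
call_events <- function(z_series, threshold = 2, min_gap_samples = 1,
                        cell_id = NA_character_, animal_id = NA_character_,
                        cell_class = NA_character_) {
  if (!is.numeric(z_series) || !length(z_series)) {
    abort("`z_series` must be a non-empty numeric vector")
  }
  if (any(!is.finite(z_series))) abort("`z_series` contains non-finite values")
  check_number(threshold, "threshold")
  check_number(min_gap_samples, "min_gap_samples", lower = 0, integerish = TRUE)

  degenerate <- isTRUE(attr(z_series, "degenerate"))
  above <- !degenerate & (z_series >= threshold)
  runs <- run_bounds(above)
  if (nrow(runs) > 1L && min_gap_samples > 1L) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap < min_gap_samples) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
    runs <- merged
  }
  peak_z <- vapply(seq_len(nrow(runs)), function(i) {
    max(z_series[runs$start[i]:runs$end[i]])
  }, numeric(1))
  events <- data.frame(start = runs$start, end = runs$end, peak_z = peak_z)
  structure(
    list(cell_id = cell_id, animal_id = animal_id, cell_class = cell_class,
         z_series = as.numeric(z_series), events = events,
         n_peaks = nrow(events), is_active = nrow(events) >= 1L,
         threshold = threshold, epoch_counts = NULL),
    class = "event_call_result"
  )
}

# Start/end (1-based, inclusive) of TRUE runs in a logical vector.
run_bounds <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' @export
print.event_call_result <- function(x, ...) {
  cat(sprintf("<event_call_result> %s: %d peak(s) at z >= %s; %s\n",
              x$cell_id, x$n_peaks, format(x$threshold),
              if (x$is_active) "active" else "inactive"))
  invisible(x)
}

#' Z-score a trace and call its events in one step
#'
#' @inheritParams zscore_trace
#' @inheritParams call_events
#' @return An `event_call_result`; see [call_events()].
#' @export
detect_calcium_events <- function(trace, threshold = 2, min_gap_samples = 1,
                                  baseline_window = NULL) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  z <- zscore_trace(trace, baseline_window = baseline_window)
  call_events(z, threshold = threshold, min_gap_samples = min_gap_samples,
              cell_id = trace$cell_id, animal_id = trace$animal_id,
              cell_class = trace$cell_class)
}

#' Count events before and after a stimulus
#'
#' Assigns each called event to the pre- or post-stimulus epoch by the time
#' of its peak sample (ties broken toward the earlier sample). Events whose
#' peak time is at or after the stimulus are "post". The two counts always
#' sum to `n_peaks`. A stimulus time recorded before the first sample puts
#' every event in the post epoch.
#'
#' @param result An `event_call_result` from [call_events()] or
#'   [detect_calcium_events()].
#' @param trace The [fluorescence_trace()] the result was computed from;
#'   must carry a `stimulus_time`.
#' @return The `event_call_result` with `epoch_counts = c(pre = , post = )`
#'   filled in.
#' @export
epoch_event_counts <- function(result, trace) {
  stopifnot(inherits(result, "event_call_result"),
            inherits(trace, "fluorescence_trace"))
  if (is.null(trace$stimulus_time)) {
    abort("`trace` has no stimulus_time; epoch counts need a stimulus")
  }
  if (length(trace$t_s) != length(result$z_series)) {
    abort("`result` and `trace` have different lengths")
  }
  ev <- result$events
  pre <- 0L
  if (nrow(ev)) {
    peak_times <- vapply(seq_len(nrow(ev)), function(i) {
      seg <- result$z_series[ev$start[i]:ev$end[i]]
      trace$t_s[ev$start[i] + which.max(seg) - 1L]
    }, numeric(1))
    pre <- sum(peak_times < trace$stimulus_time)
  }
  result$epoch_counts <- c(pre = pre, post = result$n_peaks - pre)
  result
}

#' Percentage of active cells per animal
#'
#' The binary active/inactive verdict per cell (at least one supra-threshold
#' event) aggregated per animal as `100 * active / total`, plus the mean of
#' the per-animal percentages.
#'
#' @param results List of `event_call_result` objects, each carrying an
#'   `animal_id`.
#' @return A list with `per_animal` (data frame: `animal_id`, `n_cells`,
#'   `n_active`, `percent_active`) and `mean_percent` (mean across animals).
#' @export
percent_active <- function(results) {
  stopifnot(is.list(results), length(results) > 0)
  ok <- vapply(results, inherits, logical(1), "event_call_result")
  if (!all(ok)) abort("`results` must be a list of event_call_result objects")
  animal <- vapply(results, function(r) as.character(r$animal_id), character(1))
  if (any(is.na(animal))) abort("every result must carry an animal_id")
  active <- vapply(results, function(r) r$is_active, logical(1))
  per <- do.call(rbind, lapply(split(active, animal), function(a) {
    data.frame(n_cells = length(a), n_active = sum(a),
               percent_active = 100 * sum(a) / length(a))
  }))
  per <- data.frame(animal_id = rownames(per), per, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(per_animal = per, mean_percent = mean(per$percent_active))
}

#' Cells-by-timepoints activity heatmap matrix
#'
#' Stacks per-cell z-score series into a matrix with one row per cell
#' (ordered by `cell_id`) and one column per time point, the layout used to
#' display cohort-wide changes in GCaMP intensity.
#'
#' @inheritParams percent_active
#' @param truncate If the series have unequal lengths, `TRUE` truncates all
#'   to the shortest; `FALSE` (default) raises an error.
#' @return Numeric matrix of z-scores with `cell_id` rownames.
#' @export
activity_heatmap <- function(results, truncate = FALSE) {
  stopifnot(is.list(results), length(results) > 0)
  ok <- vapply(results, inherits, logical(1), "event_call_result")
  if (!all(ok)) abort("`results` must be a list of event_call_result objects")
  lens <- vapply(results, function(r) length(r$z_series), integer(1))
  if (length(unique(lens)) > 1L) {
    if (!truncate) abort("z-series have unequal lengths; set truncate = TRUE to truncate")
    lens[] <- min(lens)
  }
  n <- min(lens)
  ids <- vapply(results, function(r) as.character(r$cell_id), character(1))
  ord <- order(ids)
  mat <- do.call(rbind, lapply(results[ord], function(r) r$z_series[seq_len(n)]))
  rownames(mat) <- ids[ord]
  mat
}
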
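#' Construct a fluorescence trace
#'
#' Regularly sampled ROI integrated-density series for one cell or
#' projection, as produced by [measure_integrated_density()] or by tracing a
#' soma/projection in an image-analysis tool. Calcium imaging traces are
#' typically sampled every 2 s for 2-3 min. An optional stimulus time marks
#' when a treatment (e.g. 4 degC water) was added.
#'
#' @param cell_id Identifier for the cell/ROI.
#' @param t_s Numeric vector of times in seconds, strictly increasing.
#' @param intensity Numeric vector of integrated densities, same length.
#' @param animal_id Identifier of the animal the cell belongs to.
#' @param cell_class One of `"drg_neuron"`, `"sensory_olc"`,
#'   `"nonsensory_olc"`.
#' @param stimulus_time Optional stimulus time in seconds.
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(cell_id, t_s, intensity,
                               animal_id = "animal1",
                               cell_class = c("drg_neuron", "sensory_olc",
                                              "nonsensory_olc"),
                               stimulus_time = NULL) {
  cell_class <- match.arg(cell_class)
  if (length(cell_id) != 1L) abort("`cell_id` must be a single identifier")
  n <- length(t_s)
  if (n < 1L) abort("a trace needs at least one sample")
  if (length(intensity) != n) {
    abort("`t_s` and `intensity` must have the same length")
  }
  if (!all(is.finite(t_s)) || !all(is.finite(intensity))) {
    abort("trace times and intensities must be finite")
  }
  if (n > 1L && any(diff(t_s) <= 0)) abort("trace times must be strictly increasing")
  check_number(stimulus_time, "stimulus_time", allow_null = TRUE)
  structure(
    list(cell_id = as.character(cell_id),
         animal_id = as.character(animal_id),
         cell_class = cell_class,
         t_s = as.numeric(t_s),
         intensity = as.numeric(intensity),
         stimulus_time = stimulus_time),
    class = "fluorescence_trace"
  )
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> %s (%s, %s): %d samples over %.1f s\n",
              x$cell_id, x$animal_id, x$cell_class, length(x$t_s),
              x$t_s[length(x$t_s)] - x$t_s[1]))
  invisible(x)
}

#' Read and write fluorescence trace tables
#'
#' Traces are exchanged as long-format CSV with columns `cell_id`,
#' `animal_id`, `cell_class`, `t_s`, `intensity`, and an optional per-animal
#' stimulus CSV with columns `animal_id`, `stimulus_time_s`.
#'
#' @param path Path of the trace CSV.
#' @param stimulus_path Optional path of the stimulus-time CSV.
#' @return `read_traces_csv()` returns a list of [fluorescence_trace()]
#'   objects.
#' @export
read_traces_csv <- function(path, stimulus_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("cell_id", "t_s", "intensity"), "trace table")
  if (is.null(df$animal_id)) df$animal_id <- "animal1"
  if (is.null(df$cell_class)) df$cell_class <- "drg_neuron"
  stim <- NULL
  if (!is.null(stimulus_path)) {
    stim <- utils::read.csv(stimulus_path, stringsAsFactors = FALSE)
    check_columns(stim, c("animal_id", "stimulus_time_s"), "stimulus table")
  }
  ids <- unique(df$cell_id)
  lapply(ids, function(id) {
    sub <- df[df$cell_id == id, , drop = FALSE]
    sub <- sub[order(sub$t_s), , drop = FALSE]
    st <- NULL
    if (!is.null(stim) && sub$animal_id[1] %in% stim$animal_id) {
      st <- stim$stimulus_time_s[match(sub$animal_id[1], stim$animal_id)]
    }
    fluorescence_trace(id, sub$t_s, sub$intensity,
                       animal_id = sub$animal_id[1],
                       cell_class = sub$cell_class[1],
                       stimulus_time = st)
  })
}

#' @rdname read_traces_csv
#' @param traces List of [fluorescence_trace()] objects.
#' @export
write_traces_csv <- function(traces, path, stimulus_path = NULL) {
  stopifnot(is.list(traces), length(traces) > 0)
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(cell_id = tr$cell_id, animal_id = tr$animal_id,
               cell_class = tr$cell_class, t_s = tr$t_s,
               intensity = tr$intensity, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(stimulus_path)) {
    stim <- unique(do.call(rbind, lapply(traces, function(tr) {
      data.frame(animal_id = tr$animal_id,
                 stimulus_time_s = tr$stimulus_time %||% NA_real_)
    })))
    utils::write.csv(stim, stimulus_path, row.names = FALSE)
  }
  invisible(path)
}
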
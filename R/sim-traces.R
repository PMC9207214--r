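#' Configuration for synthetic calcium traces
#'
#' Describes a cohort of integrated-density traces: a constant baseline plus
#' iid Gaussian noise, with calcium transients injected as
#' instantaneous-rise, exponential-decay bumps at known sample indices. The
#' defaults mirror the standard acquisition (one sample every 2 s for 2 min,
#' i.e. 60 samples) with transient amplitude six times the baseline noise sd.
#'
#' @param n_cells Number of traces to generate.
#' @param n_samples Samples per trace.
#' @param sample_interval Seconds between samples; default 2.
#' @param baseline Baseline integrated density (arbitrary units).
#' @param noise_sd Baseline noise standard deviation; must be positive.
#' @param event_times List of integer vectors (1-based sample indices), one
#'   per cell, giving transient onset samples. `NULL` means no events
#'   anywhere; a single vector is recycled to all cells.
#' @param event_amplitude Peak amplitude added at the onset sample.
#' @param event_decay Exponential decay constant in samples.
#' @param stimulus_index Optional 1-based sample index at which a stimulus
#'   was applied; recorded on each trace as a stimulus time.
#' @param animal_ids Optional character vector, one per cell, assigning cells
#'   to animals (default: all on `"animal1"`).
#' @param cell_class Class label recorded on every trace.
#' @param seed Integer seed.
#' @return A `trace_sim_config` list.
#' @export
trace_sim_config <- function(n_cells = 10,
                             n_samples = 60,
                             sample_interval = 2,
                             baseline = 100,
                             noise_sd = 5,
                             event_times = NULL,
                             event_amplitude = 30,
                             event_decay = 3,
                             stimulus_index = NULL,
                             animal_ids = NULL,
                             cell_class = "drg_neuron",
                             seed = 1) {
  check_number(n_cells, "n_cells", lower = 1, integerish = TRUE)
  check_number(n_samples, "n_samples", lower = 2, integerish = TRUE)
  check_number(sample_interval, "sample_interval")
  if (sample_interval <= 0) abort("`sample_interval` must be positive")
  check_number(baseline, "baseline")
  check_number(noise_sd, "noise_sd")
  if (noise_sd <= 0) abort("`noise_sd` must be positive")
  check_number(event_amplitude, "event_amplitude", lower = 0)
  check_number(event_decay, "event_decay")
  if (event_decay <= 0) abort("`event_decay` must be positive")
  check_number(stimulus_index, "stimulus_index", lower = 1,
               upper = n_samples, integerish = TRUE, allow_null = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  if (is.null(event_times)) {
    event_times <- rep(list(integer(0)), n_cells)
  } else if (!is.list(event_times)) {
    event_times <- rep(list(as.integer(event_times)), n_cells)
  }
  if (length(event_times) != n_cells) {
    abort("`event_times` must have one entry per cell")
  }
  for (ev in event_times) {
    if (length(ev) && (any(ev < 1) || any(ev > n_samples))) {
      abort("event times must be sample indices in [1, n_samples]")
    }
  }
  structure(list(n_cells = as.integer(n_cells),
                 n_samples = as.integer(n_samples),
                 sample_interval = sample_interval,
                 baseline = baseline, noise_sd = noise_sd,
                 event_times = lapply(event_times, as.integer),
                 event_amplitude = event_amplitude,
                 event_decay = event_decay,
                 stimulus_index = stimulus_index,
                 animal_ids = animal_ids,
                 cell_class = cell_class,
                 seed = as.integer(seed)),
            class = "trace_sim_config")
}

#' Generate synthetic calcium traces with known event ground truth
#'
#' Each trace is `baseline + noise + sum of transients`, where a transient
#' starting at sample `e` adds `event_amplitude * exp(-(i - e) / event_decay)`
#' to every sample `i >= e`. The returned truth lists every injected onset
#' once, which is sufficient for downstream sensitivity/specificity scoring.
#'
#' @param config A [trace_sim_config()].
#' @return A list with elements `traces` (list of [fluorescence_trace()])
#'   and `truth` (list of integer onset-index vectors, one per cell).
#' @export
generate_traces <- function(config) {
  stopifnot(inherits(config, "trace_sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_samples
    t_s <- (seq_len(n) - 1) * config$sample_interval
    stim <- if (!is.null(config$stimulus_index)) {
      (config$stimulus_index - 1) * config$sample_interval
    } else NULL
    animals <- config$animal_ids %||% rep("animal1", config$n_cells)
    traces <- vector("list", config$n_cells)
    for (ci in seq_len(config$n_cells)) {
      x <- config$baseline + stats::rnorm(n, 0, config$noise_sd)
      for (e in config$event_times[[ci]]) {
        idx <- e:n
        x[idx] <- x[idx] +
          config$event_amplitude * exp(-(idx - e) / config$event_decay)
      }
      traces[[ci]] <- fluorescence_trace(
        sprintf("cell_%02d", ci), t_s, x,
        animal_id = animals[ci],
        cell_class = config$cell_class,
        stimulus_time = stim
      )
    }
    list(traces = traces, truth = config$event_times)
  })
}
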
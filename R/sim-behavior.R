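#' Configuration for synthetic shiver behavior traces
#'
#' A shiver recording is emulated as Gaussian displacement noise with pure
#' sinusoidal bursts (the shiver) inside declared intervals. The frequency
#' separation between the 15 Hz tone and the low-frequency noise floor is
#' what makes detection by high-pass + RMS thresholding controllable. The
#' default window is the standard 20 s cold-water assay.
#'
#' @param duration Recording length, seconds. Default 20.
#' @param sample_rate Sampling rate, Hz. Default 60 (typical camera rate).
#' @param shiver_intervals List of `c(start, end)` second pairs inside
#'   `[0, duration]`, non-overlapping. Default one 10 s burst (fraction 0.5).
#' @param shiver_frequency Burst tone frequency, Hz. Default 15.
#' @param shiver_amplitude Burst amplitude, signal units. Default 1.
#' @param noise_sd Background noise sd. Default 0.05. May be 0 for
#'   noiseless traces.
#' @param animal_id,group Identifiers recorded on the trace.
#' @param seed Integer seed.
#' @return A `behavior_sim_config` list.
#' @export
behavior_sim_config <- function(duration = 20, sample_rate = 60,
                                shiver_intervals = list(c(5, 15)),
                                shiver_frequency = 15, shiver_amplitude = 1,
                                noise_sd = 0.05, animal_id = "animal1",
                                group = "intact", seed = 1) {
  check_number(duration, "duration")
  if (duration <= 0) abort("`duration` must be positive")
  check_number(sample_rate, "sample_rate")
  if (sample_rate <= 0) abort("`sample_rate` must be positive")
  check_number(shiver_frequency, "shiver_frequency")
  if (shiver_frequency <= 0) abort("`shiver_frequency` must be positive")
  if (shiver_frequency >= sample_rate / 2) {
    abort("`shiver_frequency` must be below the Nyquist rate")
  }
  check_number(shiver_amplitude, "shiver_amplitude", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed", integerish = TRUE)
  if (!is.list(shiver_intervals)) abort("`shiver_intervals` must be a list")
  if (length(shiver_intervals)) {
    iv <- do.call(rbind, lapply(shiver_intervals, function(x) {
      if (!is.numeric(x) || length(x) != 2L || x[1] >= x[2]) {
        abort("each shiver interval must be c(start, end) with start < end")
      }
      x
    }))
    if (any(iv < 0) || any(iv > duration)) {
      abort("shiver intervals must lie within [0, duration]")
    }
    ord <- order(iv[, 1])
    iv <- iv[ord, , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1, 1] < iv[-nrow(iv), 2])) {
      abort("shiver intervals must not overlap")
    }
    shiver_intervals <- lapply(seq_len(nrow(iv)), function(i) iv[i, ])
  }
  structure(list(duration = duration, sample_rate = sample_rate,
                 shiver_intervals = shiver_intervals,
                 shiver_frequency = shiver_frequency,
                 shiver_amplitude = shiver_amplitude,
                 noise_sd = noise_sd, animal_id = animal_id, group = group,
                 seed = as.integer(seed)),
            class = "behavior_sim_config")
}

#' Generate a synthetic behavior trace with known shiver fraction
#'
#' @param config A [behavior_sim_config()].
#' @return List with `trace` (a [behavior_trace()]) and
#'   `true_shiver_fraction` (total interval length / duration).
#' @export
generate_behavior <- function(config) {
  stopifnot(inherits(config, "behavior_sim_config"))
  withr::with_seed(config$seed, {
    n <- round(config$duration * config$sample_rate)
    t_s <- (seq_len(n) - 1) / config$sample_rate
    sig <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else numeric(n)
    total <- 0
    for (iv in config$shiver_intervals) {
      inside <- t_s >= iv[1] & t_s < iv[2]
      sig[inside] <- sig[inside] +
        config$shiver_amplitude *
        sin(2 * pi * config$shiver_frequency * (t_s[inside] - iv[1]))
      total <- total + (iv[2] - iv[1])
    }
    list(trace = behavior_trace(config$animal_id, t_s, sig,
                                group = config$group),
         true_shiver_fraction = total / config$duration)
  })
}

#' Generate a cohort of shiver recordings across experimental groups
#'
#' One trace per animal, each with a single shiver burst whose length
#' realizes the group's configured fraction of the 20 s window; the burst
#' start is drawn uniformly among feasible starts. The default fractions
#' are the reported group medians of time spent shivering: 57.5% for intact
#' animals, 53.75% for ablation controls and 2.5% after sensory OLC
#' ablation, n = 8 per group.
#'
#' @param n_per_group Animals per group. Default 8.
#' @param fractions Named fractions of the window spent shivering per group.
#' @param duration,sample_rate,shiver_frequency,shiver_amplitude,noise_sd
#'   Passed to [behavior_sim_config()].
#' @param seed Integer seed.
#' @return List with `traces` (list of [behavior_trace()]) and `truth`
#'   (data frame: `animal_id`, `group`, `true_fraction`).
#' @export
generate_shiver_cohort <- function(n_per_group = 8,
                                   fractions = c(intact = 0.575,
                                                 ablation_control = 0.5375,
                                                 sensory_olc_ablated = 0.025),
                                   duration = 20, sample_rate = 60,
                                   shiver_frequency = 15,
                                   shiver_amplitude = 1, noise_sd = 0.05,
                                   seed = 1) {
  check_number(n_per_group, "n_per_group", lower = 1, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    abort("`fractions` must be named by group")
  }
  if (any(fractions < 0) || any(fractions > 1)) {
    abort("`fractions` must lie in [0, 1]")
  }
  traces <- list()
  truth <- list()
  idx <- 0L
  for (g in names(fractions)) {
    for (a in seq_len(n_per_group)) {
      idx <- idx + 1L
      burst <- fractions[[g]] * duration
      start <- if (burst > 0 && burst < duration) {
        withr::with_seed(seed + 1000L * idx,
                         stats::runif(1, 0, duration - burst))
      } else 0
      intervals <- if (burst > 0) list(c(start, start + burst)) else list()
      cfg <- behavior_sim_config(
        duration = duration, sample_rate = sample_rate,
        shiver_intervals = intervals, shiver_frequency = shiver_frequency,
        shiver_amplitude = shiver_amplitude, noise_sd = noise_sd,
        animal_id = sprintf("%s_%02d", g, a), group = g,
        seed = seed + idx)
      sim <- generate_behavior(cfg)
      traces[[idx]] <- sim$trace
      truth[[idx]] <- data.frame(animal_id = cfg$animal_id, group = g,
                                 true_fraction = sim$true_shiver_fraction,
                                 stringsAsFactors = FALSE)
    }
  }
  list(traces = traces, truth = do.call(rbind, truth))
}
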
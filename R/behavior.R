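#' Construct a behavior trace
#'
#' A uniformly sampled displacement (or body-angle) series recorded from one
#' animal immediately after a treatment, e.g. immersion in 4 degC water. The
#' standard recording window is 20 s.
#'
#' @param animal_id Identifier.
#' @param t_s Times in seconds, uniformly spaced, strictly increasing.
#' @param signal Displacement values, same length as `t_s`.
#' @param group Experimental group: `"intact"`, `"ablation_control"`,
#'   `"sensory_olc_ablated"` or `"other"`.
#' @return An object of class `behavior_trace`.
#' @export
behavior_trace <- function(animal_id, t_s, signal,
                           group = c("intact", "ablation_control",
                                     "sensory_olc_ablated", "other")) {
  group <- match.arg(group)
  n <- length(t_s)
  if (n < 2L) abort("a behavior trace needs at least two samples")
  if (length(signal) != n) abort("`t_s` and `signal` must have the same length")
  if (!all(is.finite(t_s)) || !all(is.finite(signal))) {
    abort("times and signal must be finite")
  }
  dt <- diff(t_s)
  if (any(dt <= 0)) abort("times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    abort("behavior traces must be uniformly sampled")
  }
  structure(list(animal_id = as.character(animal_id), group = group,
                 t_s = as.numeric(t_s), signal = as.numeric(signal)),
            class = "behavior_trace")
}

#' @export
print.behavior_trace <- function(x, ...) {
  cat(sprintf("<behavior_trace> %s (%s): %d samples, %.2f s\n",
              x$animal_id, x$group, length(x$t_s), trace_duration(x)))
  invisible(x)
}

# duration counts one sample interval per sample
trace_duration <- function(trace) {
  dt <- trace$t_s[2] - trace$t_s[1]
  length(trace$t_s) * dt
}

#' Normalize a behavior recording to the standard window
#'
#' Recordings longer than `window` seconds are truncated to their first
#' `window` seconds; shorter recordings pass through unchanged with a
#' warning (their shiver fraction is then computed over the shorter
#' duration, which is algebraically the same normalization).
#'
#' @param trace A [behavior_trace()].
#' @param window Window length in seconds. Default 20.
#' @return A [behavior_trace()] no longer than `window` seconds.
#' @export
normalize_window <- function(trace, window = 20) {
  stopifnot(inherits(trace, "behavior_trace"))
  check_number(window, "window")
  if (window <= 0) abort("`window` must be positive")
  dt <- trace$t_s[2] - trace$t_s[1]
  n_keep <- round(window / dt)
  n <- length(trace$t_s)
  if (n > n_keep) {
    keep <- seq_len(n_keep)
    return(behavior_trace(trace$animal_id, trace$t_s[keep],
                          trace$signal[keep], group = trace$group))
  }
  if (n < n_keep) {
    warning(sprintf("recording for %s is shorter (%.2f s) than the %.0f s window",
                    trace$animal_id, n * dt, window), call. = FALSE)
  }
  trace
}

#' Detect shivering in a behavior trace
#'
#' Shivering is rapid small-amplitude twitching, spectrally well above slow
#' swimming undulation. The detector high-passes the displacement signal
#' with a 2nd-order Butterworth filter (zero-phase, forward-backward),
#' computes a centered sliding-window RMS (partial windows at the trace
#' edges), and marks samples whose RMS is at or above `amp_threshold`. The
#' shiver fraction is the marked share of samples.
#'
#' The default threshold of 0.5 is matched to a unit-amplitude shiver tone:
#' it is the RMS halfway in power between quiet (0) and a full burst
#' (amplitude 1, RMS 1/sqrt(2)), which makes burst-edge marking unbiased.
#' Rescale it with the signal's units.
#'
#' @param trace A [behavior_trace()].
#' @param hp_cutoff High-pass cutoff, Hz. Default 5. The sample rate must
#'   exceed twice the cutoff.
#' @param window RMS window length, seconds. Default 0.5.
#' @param amp_threshold RMS threshold in signal units. Default 0.5.
#' @return An object of class `shiver_score`: list with `animal_id`,
#'   `group`, `shiver_mask` (per-sample logical), `shiver_fraction`,
#'   `analyzed_duration` (seconds).
#' @export
detect_shiver <- function(trace, hp_cutoff = 5, window = 0.5,
                          amp_threshold = 0.5) {
  stopifnot(inherits(trace, "behavior_trace"))
  check_number(hp_cutoff, "hp_cutoff")
  if (hp_cutoff <= 0) abort("`hp_cutoff` must be positive")
  check_number(window, "window")
  if (window <= 0) abort("`window` must be positive")
  check_number(amp_threshold, "amp_threshold", lower = 0)
  dt <- trace$t_s[2] - trace$t_s[1]
  fs <- 1 / dt
  if (fs <= 2 * hp_cutoff) {
    abort(sprintf("sample rate (%.1f Hz) must exceed twice the high-pass cutoff (%.1f Hz)",
                  fs, hp_cutoff))
  }
  bf <- signal::butter(2, hp_cutoff / (fs / 2), type = "high")
  y <- signal::filtfilt(bf, trace$signal)
  n <- length(y)
  w <- max(1L, round(window * fs))
  h <- w %/% 2L
  cs <- c(0, cumsum(y^2))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  rms <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  mask <- rms >= amp_threshold
  structure(list(animal_id = trace$animal_id, group = trace$group,
                 shiver_mask = mask, shiver_fraction = mean(mask),
                 analyzed_duration = n * dt),
            class = "shiver_score")
}

#' @export
print.shiver_score <- function(x, ...) {
  cat(sprintf("<shiver_score> %s (%s): %.1f%% of %.1f s\n",
              x$animal_id, x$group, 100 * x$shiver_fraction,
              x$analyzed_duration))
  invisible(x)
}

#' Summarize shiver time per group with pairwise comparisons
#'
#' Mean percent of time spent shivering per experimental group, with Welch
#' t tests between every pair of groups that both have at least two
#' animals.
#'
#' @param scores List of `shiver_score` objects from [detect_shiver()].
#' @return List with `summary` (data frame: `group`, `n`, `mean_percent`,
#'   `sem`) and `pairwise` (data frame: `group_a`, `group_b`, `statistic`,
#'   `p_value`).
#' @export
group_behavior_summary <- function(scores) {
  stopifnot(is.list(scores), length(scores) > 0)
  ok <- vapply(scores, inherits, logical(1), "shiver_score")
  if (!all(ok)) abort("`scores` must be a list of shiver_score objects")
  grp <- vapply(scores, function(s) s$group, character(1))
  pct <- 100 * vapply(scores, function(s) s$shiver_fraction, numeric(1))
  groups <- unique(grp)
  summary <- do.call(rbind, lapply(groups, function(g) {
    x <- pct[grp == g]
    data.frame(group = g, n = length(x), mean_percent = mean(x), sem = sem(x),
               stringsAsFactors = FALSE)
  }))
  pairwise <- NULL
  if (length(groups) >= 2L) {
    combos <- utils::combn(groups, 2, simplify = FALSE)
    pairwise <- do.call(rbind, lapply(combos, function(pair) {
      x <- pct[grp == pair[1]]
      y <- pct[grp == pair[2]]
      if (length(x) < 2L || length(y) < 2L) {
        abort(sprintf("groups '%s' and '%s' need >= 2 animals each to compare",
                      pair[1], pair[2]))
      }
      ht <- welch_t(x, y)
      data.frame(group_a = pair[1], group_b = pair[2],
                 statistic = ht$statistic, p_value = ht$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(summary = summary, pairwise = pairwise)
}

#' Tactile response rate per group
#'
#' Percentage of animals in each group that exhibited a tactile response
#' (e.g. to a head touch), `100 * responders / group size`.
#'
#' @param outcomes Data frame with columns `animal_id`, `group`,
#'   `responded` (logical or 0/1).
#' @return Data frame with columns `group`, `n`, `n_responders`, `percent`.
#' @export
tactile_response_rate <- function(outcomes) {
  check_columns(outcomes, c("animal_id", "group", "responded"), "outcomes")
  if (!nrow(outcomes)) abort("`outcomes` is empty")
  resp <- as.logical(outcomes$responded)
  if (any(is.na(resp))) abort("`responded` must be logical or 0/1")
  do.call(rbind, lapply(unique(outcomes$group), function(g) {
    r <- resp[outcomes$group == g]
    data.frame(group = g, n = length(r), n_responders = sum(r),
               percent = 100 * sum(r) / length(r), stringsAsFactors = FALSE)
  }))
}
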
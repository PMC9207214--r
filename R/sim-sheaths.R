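#' Configuration for synthetic sheath morphometry tables
#'
#' Simulates the measurement design used for sheath morphometry: one
#' identified cell per fish, each cell re-measured on several consecutive
#' days with a few sheaths per day. Cell-level means are drawn per class
#' from Gaussians whose defaults reproduce the reported cohort:
#' sensory-related OLC process length 187.78 um (SEM 15.20, n = 12) versus
#' non-sensory 94.67 um (SEM 9.88, n = 11), widths 5.01 (SEM 0.23) versus
#' 7.49 um (SEM 0.41); the between-cell sd defaults are the SEMs scaled by
#' sqrt(n). Day means are equal by construction (sheaths are stable across
#' days), so the table is a null dataset for [stability_test()].
#'
#' @param n_sensory,n_nonsensory Cells (= fish) per class. Defaults 12, 11.
#' @param mean_length,mean_width Named class means, um.
#' @param sd_length,sd_width Between-cell sds, um.
#' @param days Measurement days (dpf). Default `3:6`.
#' @param sheaths_per_day Sheath measurements per cell per day. Default 3.
#' @param within_sd_frac Within-cell (sheath-to-sheath and day-to-day)
#'   noise sd as a fraction of the cell mean. Default 0.10.
#' @param seed Integer seed.
#' @return A `sheath_sim_config` list.
#' @export
sheath_sim_config <- function(n_sensory = 12, n_nonsensory = 11,
                              mean_length = c(sensory_olc = 187.78,
                                              nonsensory_olc = 94.67),
                              sd_length = c(sensory_olc = 15.20 * sqrt(12),
                                            nonsensory_olc = 9.88 * sqrt(11)),
                              mean_width = c(sensory_olc = 5.01,
                                             nonsensory_olc = 7.49),
                              sd_width = c(sensory_olc = 0.23 * sqrt(12),
                                           nonsensory_olc = 0.41 * sqrt(11)),
                              days = 3:6, sheaths_per_day = 3,
                              within_sd_frac = 0.10, seed = 1) {
  check_number(n_sensory, "n_sensory", lower = 1, integerish = TRUE)
  check_number(n_nonsensory, "n_nonsensory", lower = 1, integerish = TRUE)
  check_number(sheaths_per_day, "sheaths_per_day", lower = 1, integerish = TRUE)
  check_number(within_sd_frac, "within_sd_frac", lower = 0)
  check_number(seed, "seed", integerish = TRUE)
  if (!length(days) || any(days < 3)) abort("`days` must all be >= 3 dpf")
  structure(list(n_sensory = as.integer(n_sensory),
                 n_nonsensory = as.integer(n_nonsensory),
                 mean_length = mean_length, sd_length = sd_length,
                 mean_width = mean_width, sd_width = sd_width,
                 days = as.integer(days),
                 sheaths_per_day = as.integer(sheaths_per_day),
                 within_sd_frac = within_sd_frac,
                 seed = as.integer(seed)),
            class = "sheath_sim_config")
}

#' Generate a synthetic sheath measurement table
#'
#' @param config A [sheath_sim_config()].
#' @return A sheath data frame (see [validate_sheaths()]) with one extra
#'   truth column `cell_mean_length_um` giving each cell's generating mean.
#' @export
generate_sheaths <- function(config) {
  stopifnot(inherits(config, "sheath_sim_config"))
  withr::with_seed(config$seed, {
    rows <- list()
    counts <- c(sensory_olc = config$n_sensory,
                nonsensory_olc = config$n_nonsensory)
    for (cl in names(counts)) {
      for (ci in seq_len(counts[[cl]])) {
        cell_len <- max(1, stats::rnorm(1, config$mean_length[[cl]],
                                        config$sd_length[[cl]]))
        cell_wid <- max(0.2, stats::rnorm(1, config$mean_width[[cl]],
                                          config$sd_width[[cl]]))
        id <- sprintf("%s_%02d", sub("_olc$", "", cl), ci)
        for (d in config$days) {
          for (s in seq_len(config$sheaths_per_day)) {
            len <- max(0.5, stats::rnorm(1, cell_len,
                                         config$within_sd_frac * cell_len))
            wid <- max(0.1, stats::rnorm(1, cell_wid,
                                         config$within_sd_frac * cell_wid))
            rows[[length(rows) + 1L]] <- data.frame(
              fish_id = paste0("fish_", id), cell_id = id, cell_class = cl,
              day = d, sheath_id = sprintf("%s_d%d_s%d", id, d, s),
              length_um = len, width_um = wid,
              cell_mean_length_um = cell_len,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}
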
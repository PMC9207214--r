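#' Validate a sheath measurement table
#'
#' Sheath morphometry tables have one row per sheath per imaging day, with
#' columns `fish_id`, `cell_id`, `cell_class` (`"sensory_olc"` or
#' `"nonsensory_olc"`), `day` (days post fertilization, >= 3), `sheath_id`,
#' `length_um` and `width_um` (both positive).
#'
#' @param measurements Data frame to validate.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_sheaths <- function(measurements) {
  check_columns(measurements,
                c("fish_id", "cell_id", "cell_class", "day", "sheath_id",
                  "length_um", "width_um"),
                "measurements")
  if (any(measurements$length_um <= 0) || any(measurements$width_um <= 0)) {
    abort("sheath lengths and widths must be positive")
  }
  if (any(measurements$day < 3)) {
    abort("`day` is days post fertilization and must be >= 3")
  }
  measurements
}

#' Compare sheath morphometry between sensory and non-sensory OLCs
#'
#' Compares sheath length or width between the two cell classes with a Welch
#' (unequal-variance) two-sample t test. The unit of analysis is the cell:
#' sheath measurements are first averaged per cell, and the per-cell
#' averages are compared across cells (`unit = "sheath"` pools raw sheaths
#' instead). The sign convention is sensory minus non-sensory.
#'
#' @param measurements Sheath table; see [validate_sheaths()].
#' @param field `"length"` or `"width"`.
#' @param unit `"cell"` (default) or `"sheath"`.
#' @return List with `summary` (data frame: `cell_class`, `n`, `mean`,
#'   `sem`), `statistic` (Welch t), `df`, `p_value`, `field`, `unit`.
#' @export
group_compare <- function(measurements, field = c("length", "width"),
                          unit = c("cell", "sheath")) {
  field <- match.arg(field)
  unit <- match.arg(unit)
  measurements <- validate_sheaths(measurements)
  var <- paste0(field, "_um")
  classes <- c("sensory_olc", "nonsensory_olc")
  if (!all(classes %in% measurements$cell_class)) {
    abort("both sensory_olc and nonsensory_olc measurements are required")
  }
  values <- lapply(classes, function(cl) {
    sub <- measurements[measurements$cell_class == cl, , drop = FALSE]
    if (unit == "cell") {
      as.numeric(tapply(sub[[var]], sub$cell_id, mean))
    } else {
      sub[[var]]
    }
  })
  if (any(vapply(values, length, integer(1)) < 2L)) {
    abort("each class needs at least 2 cells (or sheaths)")
  }
  ht <- welch_t(values[[1]], values[[2]])
  summary <- data.frame(
    cell_class = classes,
    n = vapply(values, length, integer(1)),
    mean = vapply(values, mean, numeric(1)),
    sem = vapply(values, sem, numeric(1)),
    stringsAsFactors = FALSE
  )
  list(summary = summary, statistic = ht$statistic, df = ht$df,
       p_value = ht$p_value, field = field, unit = unit)
}

#' Test per-fish stability of sheath morphometry across days
#'
#' One-way ANOVA of sheath length (or width) against imaging day for a
#' single fish, asking whether the morphometry is maintained across the
#' developmental window. Requires at least two days with at least two
#' sheath measurements each. When the data have no variance at all (all
#' values identical), the ANOVA ratio is undefined; the test then reports
#' `F = 0`, `p = 1` with `degenerate = TRUE`, reading "no detectable change".
#'
#' @param measurements Sheath table for one fish (or filtered by `fish_id`).
#' @param field `"length"` or `"width"`.
#' @param fish_id Optional fish to subset; required if the table contains
#'   several fish.
#' @return List with `per_day` (data frame: `day`, `n`, `mean`, `sem`),
#'   `statistic` (F), `df1`, `df2`, `p_value`, `degenerate`, `fish_id`.
#' @export
stability_test <- function(measurements, field = c("length", "width"),
                           fish_id = NULL) {
  field <- match.arg(field)
  measurements <- validate_sheaths(measurements)
  if (!is.null(fish_id)) {
    measurements <- measurements[measurements$fish_id == fish_id, , drop = FALSE]
    if (!nrow(measurements)) abort(sprintf("no measurements for fish '%s'", fish_id))
  } else if (length(unique(measurements$fish_id)) > 1L) {
    abort("table contains several fish; pass `fish_id` (the test is per fish)")
  }
  var <- paste0(field, "_um")
  days <- sort(unique(measurements$day))
  if (length(days) < 2L) abort("stability needs measurements on at least 2 days")
  counts <- table(measurements$day)
  if (any(counts < 2L)) abort("each day needs at least 2 sheath measurements")
  per_day <- data.frame(
    day = days,
    n = as.integer(counts[as.character(days)]),
    mean = as.numeric(tapply(measurements[[var]], measurements$day, mean))[order(days)],
    sem = as.numeric(tapply(measurements[[var]], measurements$day, sem))[order(days)]
  )
  y <- measurements[[var]]
  if (sample_sd(y) == 0) {
    return(list(per_day = per_day, statistic = 0,
                df1 = length(days) - 1L, df2 = length(y) - length(days),
                p_value = 1, degenerate = TRUE,
                fish_id = measurements$fish_id[1]))
  }
  fit <- stats::aov(y ~ factor(measurements$day))
  tab <- summary(fit)[[1]]
  list(per_day = per_day, statistic = tab[["F value"]][1],
       df1 = tab[["Df"]][1], df2 = tab[["Df"]][2],
       p_value = tab[["Pr(>F)"]][1], degenerate = FALSE,
       fish_id = measurements$fish_id[1])
}

#' Maximum projection count per cell
#'
#' Given per-frame counts of extended cellular projections, returns the
#' maximum number of projections each cell displayed over the imaging
#' window.
#'
#' @param counts Data frame with columns `cell_id`, `frame`,
#'   `n_projections` (non-negative integers).
#' @return Data frame with columns `cell_id`, `max_projections`.
#' @export
max_projection_count <- function(counts) {
  check_columns(counts, c("cell_id", "n_projections"), "counts")
  if (!nrow(counts)) abort("`counts` is empty")
  if (any(counts$n_projections < 0)) abort("projection counts must be >= 0")
  mx <- tapply(counts$n_projections, counts$cell_id, max)
  data.frame(cell_id = names(mx), max_projections = as.integer(mx),
             row.names = NULL, stringsAsFactors = FALSE)
}
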
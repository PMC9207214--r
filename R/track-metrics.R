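#' Total distance migrated along a track
#'
#' Sum of Euclidean step lengths between consecutive tracked centroid
#' positions, in micrometres. A single-point track has length 0.
#'
#' @param track An [track()] object.
#' @return Path length in micrometres.
#' @export
path_length <- function(track) {
  stopifnot(inherits(track, "olc_track"))
  if (length(track$x_um) < 2L) return(0)
  sum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2))
}

#' Net displacement of a track
#'
#' Straight-line distance between the first and last tracked positions, in
#' micrometres. Always bounded above by [path_length()].
#'
#' @inheritParams path_length
#' @export
net_displacement <- function(track) {
  stopifnot(inherits(track, "olc_track"))
  n <- length(track$x_um)
  if (n < 2L) return(0)
  sqrt((track$x_um[n] - track$x_um[1])^2 + (track$y_um[n] - track$y_um[1])^2)
}

#' Count direction changes along a track
#'
#' A direction change is a turning angle of at least `angle_threshold`
#' degrees between successive displacement vectors. Because manually traced
#' centroids jitter by a pixel or two, consecutive displacement vectors
#' shorter than `min_step` micrometres are merged forward (vector summed into
#' the following step) before angles are computed, so that sub-resolution
#' wiggle is not scored as turning. A track that retains fewer than two
#' displacement vectors after merging has 0 direction changes.
#'
#' The threshold is inclusive: a turn of exactly `angle_threshold` degrees
#' counts, so the default scores right-angle and sharper turns.
#'
#' @inheritParams path_length
#' @param angle_threshold Turning angle, degrees in (0, 180], at or above
#'   which a turn is scored. Default 90.
#' @param min_step Minimum displacement-vector length in micrometres retained
#'   for angle analysis; shorter steps are merged forward. Default 2.
#' @return Integer count of direction changes.
#' @export
count_direction_changes <- function(track, angle_threshold = 90, min_step = 2) {
  stopifnot(inherits(track, "olc_track"))
  check_number(angle_threshold, "angle_threshold")
  if (angle_threshold <= 0 || angle_threshold > 180) {
    abort("`angle_threshold` must be in (0, 180] degrees")
  }
  check_number(min_step, "min_step", lower = 0)
  segs <- merged_steps(track$x_um, track$y_um, min_step)
  if (nrow(segs) < 2L) return(0L)
  n_changes <- 0L
  for (i in 2:nrow(segs)) {
    if (turning_angle_deg(segs[i - 1L, ], segs[i, ]) >= angle_threshold) {
      n_changes <- n_changes + 1L
    }
  }
  n_changes
}

# Merge consecutive displacement vectors until each retained vector is at
# least min_step long; a sub-threshold remainder at the end of the track is
# dropped as jitter. Returns a matrix with columns dx, dy.
merged_steps <- function(x, y, min_step) {
  if (length(x) < 2L) return(matrix(numeric(0), ncol = 2))
  dx <- diff(x)
  dy <- diff(y)
  out <- matrix(numeric(0), ncol = 2)
  acc <- c(0, 0)
  for (i in seq_along(dx)) {
    acc <- acc + c(dx[i], dy[i])
    nrm <- sqrt(sum(acc^2))
    if (nrm >= min_step && nrm > 0) {
      out <- rbind(out, acc)
      acc <- c(0, 0)
    }
  }
  unname(out)
}

# Angle in degrees between two step vectors (0 = no turn, 180 = reversal).
turning_angle_deg <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  cosang <- sum(a * b) / (na * nb)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Migration velocity of a track
#'
#' Total distance travelled divided by elapsed time, in micrometres per
#' minute.
#'
#' @inheritParams path_length
#' @return Velocity in micrometres per minute.
#' @export
velocity <- function(track) {
  stopifnot(inherits(track, "olc_track"))
  n <- length(track$t_min)
  if (n < 2L) abort("velocity is undefined for a single time point")
  duration <- track$t_min[n] - track$t_min[1]
  path_length(track) / duration
}

#' Delay between pioneer axon entry and DREZ contact
#'
#' Time elapsed, in hours, between the annotated entry of the pioneer sensory
#' axon into the spinal cord and the cell's first contact with the dorsal
#' root entry zone. Both annotations must be present on the track, and
#' contact may not precede entry.
#'
#' @inheritParams path_length
#' @return Delay in hours.
#' @export
contact_delay <- function(track) {
  stopifnot(inherits(track, "olc_track"))
  if (is.null(track$axon_entry_min) || is.null(track$drez_contact_min)) {
    abort("`contact_delay()` needs both `axon_entry_min` and `drez_contact_min` annotations")
  }
  delay_min <- track$drez_contact_min - track$axon_entry_min
  if (delay_min < 0) {
    abort("DREZ contact precedes axon entry; check the annotations")
  }
  delay_min / 60
}

#' Dorsal displacement after DREZ contact
#'
#' How far the cell continued dorsally after its first DREZ contact:
#' the final dorsoventral coordinate minus the coordinate at the first
#' tracked time point at or after the annotated contact time. Positive values
#' are dorsal (the y axis points ventral to dorsal).
#'
#' @inheritParams path_length
#' @return Displacement in micrometres.
#' @export
dorsal_displacement_after_contact <- function(track) {
  stopifnot(inherits(track, "olc_track"))
  if (is.null(track$drez_contact_min)) {
    abort("`dorsal_displacement_after_contact()` needs a `drez_contact_min` annotation")
  }
  tt <- track$t_min
  if (track$drez_contact_min < tt[1] || track$drez_contact_min > tt[length(tt)]) {
    abort("DREZ contact time lies outside the track's time span")
  }
  i <- which(tt >= track$drez_contact_min)[1]
  track$y_um[length(tt)] - track$y_um[i]
}

#' Overlay table for migration plots
#'
#' Translates every track so its first point is the origin and stacks them
#' into one long-form table, the form used to overlay per-cell migration
#' paths in a single plot.
#'
#' @param tracks List of [track()] objects.
#' @return A data frame with columns `track_id`, `t_min`, `dx_um`, `dy_um`.
#' @export
migration_plot_table <- function(tracks) {
  stopifnot(is.list(tracks))
  if (!length(tracks)) {
    return(data.frame(track_id = character(0), t_min = numeric(0),
                      dx_um = numeric(0), dy_um = numeric(0)))
  }
  do.call(rbind, lapply(tracks, function(tr) {
    stopifnot(inherits(tr, "olc_track"))
    data.frame(track_id = tr$track_id,
               t_min = tr$t_min,
               dx_um = tr$x_um - tr$x_um[1],
               dy_um = tr$y_um - tr$y_um[1],
               stringsAsFactors = FALSE)
  }))
}

#' Per-track migration feature summary
#'
#' Extracts the scalar features used to profile OLC migration: total
#' distance, number of direction changes, net displacement, duration and
#' velocity. Velocity is `NA` for tracks with a single time point.
#'
#' @inheritParams count_direction_changes
#' @return A one-row data frame.
#' @export
track_features <- function(track, angle_threshold = 90, min_step = 2) {
  stopifnot(inherits(track, "olc_track"))
  n <- length(track$t_min)
  duration <- if (n > 1L) track$t_min[n] - track$t_min[1] else 0
  data.frame(
    track_id = track$track_id,
    total_distance = path_length(track),
    n_direction_changes = count_direction_changes(track, angle_threshold, min_step),
    net_displacement = net_displacement(track),
    duration = duration,
    velocity = if (duration > 0) path_length(track) / duration else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' @rdname track_features
#' @param tracks List of [track()] objects.
#' @export
featurize_tracks <- function(tracks, angle_threshold = 90, min_step = 2) {
  stopifnot(is.list(tracks), length(tracks) > 0)
  do.call(rbind, lapply(tracks, track_features,
                        angle_threshold = angle_threshold,
                        min_step = min_step))
}
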
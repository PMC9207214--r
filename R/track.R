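#' Construct a migration track
#'
#' A track is the time-ordered 2-D path of one cell-body centroid, as produced
#' by manual centroid tracking of lateral-view spinal cord time-lapse
#' z-projections. Coordinates are in micrometres with x increasing anterior to
#' posterior and y increasing ventral to dorsal; times are minutes from the
#' start of the imaging window. Two optional event annotations, scored
#' visually from the movies, time the entry of the pioneer sensory axon into
#' the spinal cord and the first contact of the cell with the dorsal root
#' entry zone (DREZ).
#'
#' @param track_id Identifier for the cell (character scalar).
#' @param t_min Numeric vector of time stamps in minutes, strictly increasing.
#' @param x_um,y_um Numeric vectors of centroid coordinates in micrometres,
#'   same length as `t_min`.
#' @param axon_entry_min Optional time (minutes) of pioneer axon entry.
#' @param drez_contact_min Optional time (minutes) of first DREZ contact.
#' @return An object of class `olc_track`.
#' @seealso [path_length()], [count_direction_changes()], [velocity()],
#'   [contact_delay()]
#' @examples
#' tr <- track("opc1", t_min = c(0, 5, 10), x_um = c(0, 3, 3), y_um = c(0, 4, 9))
#' path_length(tr)
#' @export
track <- function(track_id, t_min, x_um, y_um,
                  axon_entry_min = NULL, drez_contact_min = NULL) {
  if (length(track_id) != 1L) abort("`track_id` must be a single identifier")
  n <- length(t_min)
  if (n < 1L) abort("a track needs at least one point")
  if (length(x_um) != n || length(y_um) != n) {
    abort("`t_min`, `x_um` and `y_um` must have the same length")
  }
  if (!all(is.finite(t_min)) || !all(is.finite(x_um)) || !all(is.finite(y_um))) {
    abort("track coordinates and times must be finite")
  }
  if (n > 1L && any(diff(t_min) <= 0)) {
    abort("track times must be strictly increasing")
  }
  check_number(axon_entry_min, "axon_entry_min", allow_null = TRUE)
  check_number(drez_contact_min, "drez_contact_min", allow_null = TRUE)
  structure(
    list(track_id = as.character(track_id),
         t_min = as.numeric(t_min),
         x_um = as.numeric(x_um),
         y_um = as.numeric(y_um),
         axon_entry_min = axon_entry_min,
         drez_contact_min = drez_contact_min),
    class = "olc_track"
  )
}

#' @export
print.olc_track <- function(x, ...) {
  cat(sprintf("<olc_track> %s: %d points, %.1f-%.1f min\n",
              x$track_id, length(x$t_min), x$t_min[1],
              x$t_min[length(x$t_min)]))
  if (!is.null(x$axon_entry_min)) {
    cat(sprintf("  axon entry at %.1f min\n", x$axon_entry_min))
  }
  if (!is.null(x$drez_contact_min)) {
    cat(sprintf("  DREZ contact at %.1f min\n", x$drez_contact_min))
  }
  invisible(x)
}

#' @export
as.data.frame.olc_track <- function(x, ...) {
  data.frame(track_id = x$track_id,
             frame = seq_along(x$t_min),
             t_min = x$t_min,
             x_um = x$x_um,
             y_um = x$y_um,
             stringsAsFactors = FALSE)
}

#' Read and write track tables
#'
#' Tracks are exchanged as long-format CSV with columns `track_id`, `frame`,
#' `t_min`, `x_um`, `y_um` (one row per tracked time point), optionally
#' accompanied by an annotation CSV with columns `track_id`,
#' `axon_entry_min`, `drez_contact_min` holding visually scored event times.
#'
#' @param path Path of the track CSV.
#' @param annotations_path Optional path of the annotation CSV.
#' @return `read_tracks_csv()` returns a list of [track()] objects;
#'   `write_tracks_csv()` invisibly returns `path`.
#' @export
read_tracks_csv <- function(path, annotations_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("track_id", "t_min", "x_um", "y_um"), "track table")
  ann <- NULL
  if (!is.null(annotations_path)) {
    ann <- utils::read.csv(annotations_path, stringsAsFactors = FALSE)
    check_columns(ann, "track_id", "annotation table")
  }
  ids <- unique(df$track_id)
  lapply(ids, function(id) {
    sub <- df[df$track_id == id, , drop = FALSE]
    sub <- sub[order(sub$t_min), , drop = FALSE]
    entry <- contact <- NULL
    if (!is.null(ann) && id %in% ann$track_id) {
      row <- ann[match(id, ann$track_id), ]
      if (!is.null(row$axon_entry_min) && is.finite(row$axon_entry_min)) {
        entry <- row$axon_entry_min
      }
      if (!is.null(row$drez_contact_min) && is.finite(row$drez_contact_min)) {
        contact <- row$drez_contact_min
      }
    }
    track(id, sub$t_min, sub$x_um, sub$y_um,
          axon_entry_min = entry, drez_contact_min = contact)
  })
}

#' @rdname read_tracks_csv
#' @param tracks List of [track()] objects.
#' @export
write_tracks_csv <- function(tracks, path, annotations_path = NULL) {
  stopifnot(is.list(tracks), length(tracks) > 0)
  df <- do.call(rbind, lapply(tracks, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(annotations_path)) {
    ann <- do.call(rbind, lapply(tracks, function(tr) {
      data.frame(track_id = tr$track_id,
                 axon_entry_min = tr$axon_entry_min %||% NA_real_,
                 drez_contact_min = tr$drez_contact_min %||% NA_real_)
    }))
    utils::write.csv(ann, annotations_path, row.names = FALSE)
  }
  invisible(path)
}
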
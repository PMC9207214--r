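#' Published timing and behavior count tables
#'
#' Two small tables reconstructed from values printed in the study this
#' workflow quantifies, shipped so the corresponding statistics can be
#' recomputed from first inputs.
#'
#' `drez_contact_tracks()` returns the six imaged OPCs' DREZ-contact timing
#' as annotated [track()] objects (axon entry at 0 min; contact at the
#' published per-OPC delay, converted to minutes), suitable for
#' [contact_delay()]. `tactile_outcomes()` returns the 24-animal tactile
#' assay outcome table (8 animals per group with the published responder
#' counts), suitable for [tactile_response_rate()].
#'
#' @return See above; a list of tracks, or a data frame.
#' @export
drez_contact_tracks <- function() {
  path <- system.file("extdata", "drez_contact_times.csv",
                      package = "olcquant", mustWork = TRUE)
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(ann)), function(i) {
    # positions were not published; the timing annotations are the data
    track(ann$track_id[i],
          t_min = c(ann$axon_entry_min[i], ann$drez_contact_min[i]),
          x_um = c(0, 0), y_um = c(0, 0),
          axon_entry_min = ann$axon_entry_min[i],
          drez_contact_min = ann$drez_contact_min[i])
  })
}

#' @rdname drez_contact_tracks
#' @export
tactile_outcomes <- function() {
  path <- system.file("extdata", "tactile_outcomes.csv",
                      package = "olcquant", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
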
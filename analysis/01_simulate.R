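#!/usr/bin/env Rscript
# Stage 1 — generate the seeded synthetic study datasets.
#
# Every downstream analysis script reads the tables written here. The
# generators encode the study conditions: ~21 tracked OLCs in three
# migration profiles, a 21-cell / 5-animal calcium cohort per temperature
# condition, 12 + 11 sheath-measured cells over 3-6 dpf, and 8 animals per
# behavior group. All randomness flows from SEED.

library(olcquant)

SEED <- 20260922L %% 100000L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("simulating migration tracks (3 clusters x 7 cells) ...")
tracks <- generate_tracks(track_sim_config(seed = SEED))
write_tracks_csv(tracks$tracks, file.path(out, "tracks.csv"))
write.csv(data.frame(track_id = vapply(tracks$tracks, `[[`, "", "track_id"),
                     true_cluster = tracks$labels),
          file.path(out, "track_labels.csv"), row.names = FALSE)

message("simulating calcium cohorts (4 degC and 23 degC conditions) ...")
cold <- generate_calcium_cohort(p_active = 0.96, seed = SEED + 1L)
room <- generate_calcium_cohort(p_active = 0.066, seed = SEED + 2L)
write_traces_csv(cold$traces, file.path(out, "traces_cold.csv"))
write_traces_csv(room$traces, file.path(out, "traces_room.csv"))
write.csv(cold$truth, file.path(out, "traces_cold_truth.csv"), row.names = FALSE)
write.csv(room$truth, file.path(out, "traces_room_truth.csv"), row.names = FALSE)

message("simulating sheath morphometry table (12 sensory / 11 non-sensory cells) ...")
sheaths <- generate_sheaths(sheath_sim_config(seed = SEED + 3L))
write.csv(sheaths, file.path(out, "sheaths.csv"), row.names = FALSE)

message("simulating shiver behavior cohort (3 groups x 8 animals) ...")
cohort <- generate_shiver_cohort(seed = SEED + 4L)
beh <- do.call(rbind, lapply(cohort$traces, function(tr) {
  data.frame(animal_id = tr$animal_id, group = tr$group,
             t_s = tr$t_s, signal = tr$signal)
}))
write.csv(beh, file.path(out, "behavior.csv"), row.names = FALSE)
write.csv(cohort$truth, file.path(out, "behavior_truth.csv"), row.names = FALSE)

message("simulating a small moving-blob image stack with ROI truth ...")
roi <- roi_spec("cell1", "polygon",
                rbind(c(2.5, 2.5), c(2.5, 13.5), c(13.5, 13.5), c(13.5, 2.5)),
                background = rbind(c(16.5, 16.5), c(16.5, 23.5),
                                   c(23.5, 23.5), c(23.5, 16.5)))
blob <- generate_image_stack(
  n_frames = 12, height = 24, width = 24,
  blob_path = cbind(seq(4, 12, length.out = 12), seq(4, 12, length.out = 12)),
  blob_amplitude = 120, blob_sigma = 1.8, background_level = 20,
  noise_sd = 2, roi = roi, seed = SEED + 5L)
write_stack_tiff(blob$stack, file.path(out, "blob_stack.tif"))
write_roi_json(list(roi), file.path(out, "blob_roi.json"))
write.csv(data.frame(frame = seq_along(blob$truth), truth_id = blob$truth),
          file.path(out, "blob_truth.csv"), row.names = FALSE)

message("done; tables under ", out)
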
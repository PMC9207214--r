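#!/usr/bin/env Rscript
# Stage 6 — behavior: shiver scoring per animal and group, detector
# validation against generator truth, and tactile response proportions
# from the published outcome counts.

library(olcquant)

out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

beh <- read.csv("results/data/behavior.csv", stringsAsFactors = FALSE)
truth <- read.csv("results/data/behavior_truth.csv", stringsAsFactors = FALSE)

scores <- lapply(split(beh, beh$animal_id), function(sub) {
  tr <- behavior_trace(sub$animal_id[1], sub$t_s, sub$signal,
                       group = sub$group[1])
  detect_shiver(normalize_window(tr, 20))
})
score_df <- do.call(rbind, lapply(scores, function(s) {
  data.frame(animal_id = s$animal_id, group = s$group,
             shiver_fraction = s$shiver_fraction)
}))
score_df$true_fraction <- truth$true_fraction[match(score_df$animal_id,
                                                    truth$animal_id)]
write.csv(score_df, file.path(out, "shiver_scores.csv"), row.names = FALSE)
message(sprintf("detector vs truth: max |error| = %.3f across %d animals",
                max(abs(score_df$shiver_fraction - score_df$true_fraction)),
                nrow(score_df)))

gsum <- group_behavior_summary(unname(scores))
write.csv(gsum$summary, file.path(out, "shiver_group_summary.csv"),
          row.names = FALSE)
write.csv(gsum$pairwise, file.path(out, "shiver_pairwise.csv"),
          row.names = FALSE)
for (i in seq_len(nrow(gsum$summary))) {
  message(sprintf("  %-22s %5.2f%% of time shivering (n = %d)",
                  gsum$summary$group[i], gsum$summary$mean_percent[i],
                  gsum$summary$n[i]))
}

rates <- tactile_response_rate(tactile_outcomes())
write.csv(rates, file.path(out, "tactile_rates.csv"), row.names = FALSE)
for (i in seq_len(nrow(rates))) {
  message(sprintf("  tactile response %-22s %5.1f%% (%d/%d)",
                  rates$group[i], rates$percent[i], rates$n_responders[i],
                  rates$n[i]))
}
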
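test_that("zero-noise tracks reproduce configured targets exactly", {
  cfg <- track_sim_config(n_per_cluster = 1,
                          cluster_specs = list(c(100, 0, 0)), seed = 2)
  sim <- generate_tracks(cfg)
  f <- track_features(sim$tracks[[1]])
  expect_equal(f$total_distance, 100)
  expect_equal(f$n_direction_changes, 0L)

  cfg3 <- track_sim_config(n_per_cluster = 2,
                           cluster_specs = list(c(85, 1, 0), c(70, 5, 0),
                                                c(260, 4, 0)),
                           seed = 9)
  feats <- featurize_tracks(generate_tracks(cfg3)$tracks)
  expect_equal(feats$total_distance, rep(c(85, 70, 260), each = 2))
  expect_equal(feats$n_direction_changes, rep(c(1L, 5L, 4L), each = 2))
})

test_that("noisy track feature means stay near targets (brute-force featurizer)", {
  cfg <- track_sim_config(n_per_cluster = 20,
                          cluster_specs = list(c(50, 1, 2), c(300, 6, 2)),
                          seed = 7)
  sim <- generate_tracks(cfg)
  # recompute features with the independent oracles, not the package
  pl <- vapply(sim$tracks, function(tr) oracle_path_length(tr$x_um, tr$y_um),
               numeric(1))
  dc <- vapply(sim$tracks,
               function(tr) oracle_direction_changes(tr$x_um, tr$y_um),
               numeric(1))
  for (ci in 1:2) {
    target <- cfg$cluster_specs[[ci]]
    in_c <- sim$labels == ci
    expect_lt(abs(mean(pl[in_c]) - target[1]), 3 * sd(pl[in_c]))
    expect_lt(abs(mean(dc[in_c]) - target[2]), 3 * max(sd(dc[in_c]), 0.5))
  }
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- track_sim_config(seed = 123)
  expect_identical(generate_tracks(cfg), generate_tracks(cfg))

  tcfg <- trace_sim_config(n_cells = 3, event_times = list(5L, integer(0), 40L),
                           seed = 55)
  expect_identical(generate_traces(tcfg), generate_traces(tcfg))

  bcfg <- behavior_sim_config(seed = 8)
  expect_identical(generate_behavior(bcfg), generate_behavior(bcfg))

  expect_identical(generate_sheaths(sheath_sim_config(seed = 4)),
                   generate_sheaths(sheath_sim_config(seed = 4)))
})

test_that("invalid generator configurations are rejected", {
  expect_error(track_sim_config(n_frames = 0), "at least 2")
  expect_error(track_sim_config(n_frames = -5), "at least 2")
  expect_error(track_sim_config(cluster_specs = list(c(100, 20, 0))),
               "n_frames - 2")
  expect_error(trace_sim_config(noise_sd = 0), "positive")
  expect_error(trace_sim_config(noise_sd = -1), "positive")
  expect_error(trace_sim_config(n_samples = 10, event_times = list(11L),
                                n_cells = 1), "sample indices")
  expect_error(behavior_sim_config(shiver_intervals = list(c(0, 10), c(5, 15))),
               "overlap")
  expect_error(behavior_sim_config(shiver_intervals = list(c(-1, 5))),
               "within")
})

test_that("trace truth lists exactly the injected events", {
  none <- generate_traces(trace_sim_config(n_cells = 4, seed = 6))
  expect_true(all(vapply(none$truth, length, integer(1)) == 0L))

  ev <- list(c(10L, 40L), 25L, integer(0))
  sim <- generate_traces(trace_sim_config(n_cells = 3, event_times = ev,
                                          seed = 11))
  expect_identical(sim$truth, ev)
  # a trace is baseline + noise + transient: the onset sample of the big
  # first event clearly dominates its neighborhood
  tr <- sim$traces[[2]]
  expect_equal(which.max(tr$intensity), 25L)
})

test_that("events injected only after the stimulus leave the pre epoch empty", {
  sim <- generate_traces(trace_sim_config(n_cells = 2, stimulus_index = 30L,
                                          event_times = list(c(35L, 50L), 45L),
                                          event_amplitude = 100, seed = 20))
  for (i in 1:2) {
    r <- epoch_event_counts(detect_calcium_events(sim$traces[[i]]),
                            sim$traces[[i]])
    expect_equal(unname(r$epoch_counts["pre"]), 0L)
    expect_equal(sum(r$epoch_counts), r$n_peaks)
  }
})

test_that("a high-SNR injected event is detected downstream", {
  cfg <- trace_sim_config(n_cells = 1, event_times = list(30L),
                          event_amplitude = 100, noise_sd = 5, seed = 17)
  sim <- generate_traces(cfg)
  r <- detect_calcium_events(sim$traces[[1]])
  expect_true(r$is_active)
  expect_true(any(r$events$start <= 30 & r$events$end >= 30))
})

test_that("image stack truth is analytic and exact in degenerate cases", {
  sq9 <- roi_spec("sq", "polygon",
                  rbind(c(-0.5, -0.5), c(-0.5, 2.5), c(2.5, 2.5), c(2.5, -0.5)))
  flat <- generate_image_stack(3, 8, 8, cbind(rep(4, 3), rep(4, 3)),
                               blob_amplitude = 0, background_level = 5,
                               roi = sq9)
  expect_equal(flat$truth, rep(5 * 9, 3))

  # single bright pixel inside a 9-px ROI over zero background
  px <- array(0, dim = c(1, 5, 5))
  px[1, 2, 2] <- 10
  st <- image_stack(px)
  expect_equal(measure_integrated_density(st, sq9)$intensity, 10)

  expect_error(generate_image_stack(2, 8, 8, cbind(c(4, 20), c(4, 4))),
               "inside the frame")
})

test_that("measured density on a noisy seeded stack tracks the analytic truth", {
  sq <- roi_spec("sq", "polygon",
                 rbind(c(1.5, 1.5), c(1.5, 8.5), c(8.5, 8.5), c(8.5, 1.5)))
  sim <- generate_image_stack(5, 12, 12,
                              cbind(seq(3, 8, length.out = 5),
                                    seq(3, 8, length.out = 5)),
                              blob_amplitude = 40, blob_sigma = 1.2,
                              background_level = 10, noise_sd = 1,
                              roi = sq, seed = 31)
  got <- measure_integrated_density(sim$stack, sq)$intensity
  # ROI has 49 px; mean-zero pixel noise of sd 1 gives sd 7 on the sum
  expect_true(all(abs(got - sim$truth) < 5 * sqrt(sum(rasterize_roi(sq, 12, 12)))))
})

test_that("behavior generator encodes the configured shiver fraction", {
  none <- generate_behavior(behavior_sim_config(shiver_intervals = list(),
                                                seed = 3))
  expect_equal(none$true_shiver_fraction, 0)
  half <- generate_behavior(behavior_sim_config(shiver_intervals = list(c(5, 15)),
                                                seed = 3))
  expect_equal(half$true_shiver_fraction, 0.5)
  # detector recovers the fraction on a noiseless burst trace
  clean <- generate_behavior(behavior_sim_config(shiver_intervals = list(c(2, 12)),
                                                 noise_sd = 0, seed = 3))
  sc <- detect_shiver(clean$trace)
  expect_lt(abs(sc$shiver_fraction - clean$true_shiver_fraction), 0.05)
})
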
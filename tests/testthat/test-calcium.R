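trace_of <- function(values, ..., cell_id = "c1", interval = 2) {
  fluorescence_trace(cell_id, (seq_along(values) - 1) * interval, values, ...)
}

test_that("z-scoring standardizes against the whole-trace mean and sample sd", {
  z <- zscore_trace(trace_of(c(1, 2, 3)))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_false(attr(z, "degenerate"))

  flat <- zscore_trace(trace_of(rep(7, 10)))
  expect_true(attr(flat, "degenerate"))
  expect_equal(as.numeric(flat), rep(0, 10))
  expect_equal(call_events(flat)$n_peaks, 0L)

  expect_error(zscore_trace(trace_of(5)), "two samples")

  withr::with_seed(3, x <- rnorm(60, 100, 12))
  z <- zscore_trace(trace_of(x))
  # two-pass hand computation
  m <- sum(x) / 60
  s <- sqrt(sum((x - m)^2) / 59)
  expect_equal(as.numeric(z), (x - m) / s)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("a baseline window restricts the z reference", {
  tr <- trace_of(c(10, 10, 10, 12, 30, 30))
  z <- zscore_trace(tr, baseline_window = c(0, 6))  # first four samples
  ref <- c(10, 10, 10, 12)
  expect_equal(as.numeric(z), (tr$intensity - mean(ref)) / sd(ref))
  expect_error(zscore_trace(tr, baseline_window = c(0, 1)), "two samples")
})

test_that("event calling groups supra-threshold runs, threshold inclusive", {
  quiet <- call_events(c(-1, 0.5, 1.9, 0, 1))
  expect_equal(quiet$n_peaks, 0L)
  expect_false(quiet$is_active)

  edge <- call_events(c(0, 2, 0))
  expect_equal(edge$n_peaks, 1L)
  expect_equal(edge$events$start, 2L)
  expect_equal(edge$events$peak_z, 2)
  expect_true(edge$is_active)

  two <- call_events(c(3, 3, 0, 0, 2.5, 0))
  expect_equal(two$n_peaks, 2L)
  expect_equal(two$events$start, c(1L, 5L))
  expect_equal(two$events$end, c(2L, 5L))
  # a 1-sample gap is swallowed when min_gap_samples = 2
  merged <- call_events(c(3, 3, 0, 2.5, 0), min_gap_samples = 2)
  expect_equal(merged$n_peaks, 1L)
  expect_equal(merged$events$end, 4L)

  expect_error(call_events(c(1, NA, 2)), "non-finite")
})

test_that("event calling matches a brute-force run scanner on random series", {
  withr::with_seed(37, {
    for (i in 1:50) {
      z <- runif(40, -4, 4)
      got <- call_events(z)$events
      want <- oracle_call_runs(z)
      expect_equal(nrow(got), length(want))
      for (j in seq_along(want)) {
        expect_equal(c(got$start[j], got$end[j]), want[[j]])
      }
    }
  })
})

test_that("event calls are invariant to affine rescaling of the raw trace", {
  withr::with_seed(53, x <- rnorm(60, 100, 5) + c(rep(0, 30), 40, 30, 20, rep(0, 27)))
  a <- detect_calcium_events(trace_of(x))
  b <- detect_calcium_events(trace_of(3.7 * x + 150))
  expect_equal(a$events, b$events)
  expect_equal(a$z_series, b$z_series, tolerance = 1e-10)
})

test_that("epoch counts split events at the stimulus and always sum to n_peaks", {
  x <- c(rep(10, 10), 50, rep(10, 19), 60, rep(10, 29))
  tr <- trace_of(x, stimulus_time = 40)
  r <- epoch_event_counts(detect_calcium_events(tr), tr)
  expect_equal(r$epoch_counts, c(pre = 1L, post = 1L))

  early <- trace_of(x, stimulus_time = -5)  # stimulus before the recording
  r2 <- epoch_event_counts(detect_calcium_events(early), early)
  expect_equal(unname(r2$epoch_counts["pre"]), 0L)
  expect_equal(sum(r2$epoch_counts), r2$n_peaks)

  no_stim <- trace_of(x)
  expect_error(epoch_event_counts(detect_calcium_events(no_stim), no_stim),
               "stimulus")
})

test_that("percent active aggregates the binary verdict per animal", {
  mk <- function(animal, active) {
    z <- if (active) c(rep(0, 5), 3, rep(0, 4)) else rep(0, 10)
    call_events(z, cell_id = paste0(animal, sample.int(1e6, 1)),
                animal_id = animal)
  }
  withr::with_seed(5, {
    results <- c(lapply(1:3, function(i) mk("a1", i <= 3)),   # 3/3
                 lapply(1:4, function(i) mk("a2", i <= 3)),   # 3/4
                 lapply(1:5, function(i) mk("a3", FALSE)))    # 0/5
  })
  pa <- percent_active(results)
  expect_equal(pa$per_animal$percent_active[pa$per_animal$animal_id == "a2"], 75)
  expect_equal(pa$per_animal$percent_active[pa$per_animal$animal_id == "a3"], 0)
  expect_equal(pa$mean_percent, mean(c(100, 75, 0)))
})

test_that("the activity heatmap is the stacked z matrix, row-stable by cell id", {
  sim <- generate_traces(trace_sim_config(n_cells = 3,
                                          event_times = list(10L, integer(0), 30L),
                                          seed = 61))
  results <- lapply(sim$traces, detect_calcium_events)
  hm <- activity_heatmap(results)
  expect_equal(dim(hm), c(3, 60))
  expect_equal(rownames(hm), sort(vapply(sim$traces, `[[`, "", "cell_id")))
  for (i in 1:3) {
    expect_equal(unname(hm[sim$traces[[i]]$cell_id, ]),
                 as.numeric(zscore_trace(sim$traces[[i]])))
  }

  flat <- lapply(1:2, function(i) {
    detect_calcium_events(trace_of(rep(5, 10), cell_id = paste0("f", i)))
  })
  expect_true(all(activity_heatmap(flat) == 0))

  ragged <- c(results[1], list(detect_calcium_events(trace_of(rnorm(30, 10)))))
  expect_error(activity_heatmap(ragged), "unequal")
  expect_equal(ncol(activity_heatmap(ragged, truncate = TRUE)), 30)
})

test_that("trace CSV round-trips with stimulus times", {
  tmp <- withr::local_tempdir()
  sim <- generate_traces(trace_sim_config(n_cells = 2, stimulus_index = 20L,
                                          seed = 71))
  p <- file.path(tmp, "traces.csv")
  s <- file.path(tmp, "stim.csv")
  write_traces_csv(sim$traces, p, s)
  back <- read_traces_csv(p, s)
  expect_equal(back, sim$traces)
})
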
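test_that("path length sums Euclidean steps and handles degenerate tracks", {
  tr <- track("a", c(0, 5), c(0, 3), c(0, 4))
  expect_equal(path_length(tr), 5)
  expect_equal(path_length(track("b", 0, 1, 1)), 0)
  expect_equal(net_displacement(tr), 5)

  withr::with_seed(42, {
    for (i in 1:20) {
      tr <- random_track(50)
      expect_equal(path_length(tr), oracle_path_length(tr$x_um, tr$y_um))
      expect_gte(path_length(tr), net_displacement(tr) - 1e-9)
    }
  })
})

test_that("direction changes score turning angles at or above the threshold", {
  straight <- track("s", c(0, 5, 10, 15), c(0, 10, 20, 30), c(0, 0, 0, 0))
  expect_equal(count_direction_changes(straight), 0L)

  out_back <- track("ob", c(0, 5, 10), c(0, 10, 0), c(0, 0, 0))
  expect_equal(count_direction_changes(out_back), 1L)

  right_angle <- track("ra", c(0, 5, 10), c(0, 10, 10), c(0, 0, 10))
  expect_equal(count_direction_changes(right_angle, angle_threshold = 90), 1L)

  expect_error(count_direction_changes(straight, angle_threshold = 0), "0, 180")
  expect_error(count_direction_changes(straight, angle_threshold = 181), "0, 180")
})

test_that("sub-min_step jitter is merged before angle analysis", {
  # a 10 um run east, a 1.4 um backward jitter, then 10 um east again:
  # unmerged, the jitter step makes two 135-degree turns; merged, the
  # track is effectively straight
  tr <- track("j", c(0, 5, 10, 15), c(0, 10, 9, 19), c(0, 0, -1, -1))
  expect_equal(count_direction_changes(tr, min_step = 2), 0L)
  expect_equal(count_direction_changes(tr, min_step = 0), 2L)
})

test_that("direction changes match the brute-force oracle on random tracks", {
  withr::with_seed(7, {
    for (i in 1:50) {
      tr <- random_track(30, scale = 4)
      expect_equal(count_direction_changes(tr),
                   oracle_direction_changes(tr$x_um, tr$y_um))
      expect_equal(count_direction_changes(tr, angle_threshold = 45, min_step = 1),
                   oracle_direction_changes(tr$x_um, tr$y_um, 45, 1))
    }
  })
})

test_that("direction changes are invariant to rotation, translation and scaling", {
  withr::with_seed(13, {
    tr <- random_track(25, scale = 5)
    base <- count_direction_changes(tr)
    th <- runif(1, 0, 2 * pi)
    rx <- cos(th) * tr$x_um - sin(th) * tr$y_um + 40
    ry <- sin(th) * tr$x_um + cos(th) * tr$y_um - 17
    rotated <- track("rot", tr$t_min, rx, ry)
    expect_equal(count_direction_changes(rotated), base)
    scaled <- track("scl", tr$t_min, 3 * tr$x_um, 3 * tr$y_um)
    # scaling up can only keep or promote steps past min_step; with a
    # threshold scaled alongside the track the count is identical
    expect_equal(count_direction_changes(scaled, min_step = 6), base)
  })
})

test_that("velocity is path length over elapsed time", {
  tr <- track("v", c(0, 10), c(0, 3), c(0, 4))
  expect_equal(velocity(tr), 0.5)
  still <- track("still", c(0, 60), c(2, 2), c(3, 3))
  expect_equal(velocity(still), 0)
  expect_error(velocity(track("one", 0, 0, 0)), "single time point")
})

test_that("contact delay converts annotation differences to hours", {
  tr <- track("opc", c(0, 315), c(0, 1), c(0, 1),
              axon_entry_min = 60, drez_contact_min = 315)
  expect_equal(contact_delay(tr), 4.25)
  same <- track("eq", c(0, 100), c(0, 1), c(0, 1),
                axon_entry_min = 50, drez_contact_min = 50)
  expect_equal(contact_delay(same), 0)
  expect_error(contact_delay(track("na", c(0, 10), c(0, 1), c(0, 1))),
               "annotation")
  neg <- track("neg", c(0, 100), c(0, 1), c(0, 1),
               axon_entry_min = 90, drez_contact_min = 30)
  expect_error(contact_delay(neg), "precedes")
})

test_that("dorsal displacement is measured from the first sample at/after contact", {
  tr <- track("d", c(0, 10, 20, 30), c(0, 1, 2, 3), c(0, 5, 12.1, 22.1),
              drez_contact_min = 10)
  expect_equal(dorsal_displacement_after_contact(tr), 17.1)
  flat <- track("f", c(0, 10, 20), c(0, 1, 2), c(4, 4, 4), drez_contact_min = 5)
  expect_equal(dorsal_displacement_after_contact(flat), 0)
  out <- track("o", c(0, 10), c(0, 1), c(0, 1), drez_contact_min = 99)
  expect_error(dorsal_displacement_after_contact(out), "span")
})

test_that("migration plot table translates every track to the origin", {
  t1 <- track("t1", c(0, 5, 10), c(10, 13, 13), c(-2, -2, 3))
  t2 <- track("t2", c(0, 5), c(100, 104), c(50, 47))
  tab <- migration_plot_table(list(t1, t2))
  expect_equal(tab$dx_um[tab$track_id == "t1"], c(0, 3, 3))
  expect_equal(tab$dy_um[tab$track_id == "t1"], c(0, 0, 5))
  expect_equal(tab[tab$track_id == "t2", c("dx_um", "dy_um")],
               data.frame(dx_um = c(0, 4), dy_um = c(0, -3), row.names = 4:5))
  # translation invariance
  shifted <- track("t1", t1$t_min, t1$x_um + 77, t1$y_um - 13)
  expect_equal(migration_plot_table(list(shifted))[, -1],
               migration_plot_table(list(t1))[, -1])
})

test_that("metrics are invariant to a constant time offset", {
  withr::with_seed(3, tr <- random_track(20))
  shifted <- track(tr$track_id, tr$t_min + 123, tr$x_um, tr$y_um)
  expect_equal(path_length(shifted), path_length(tr))
  expect_equal(velocity(shifted), velocity(tr))
  expect_equal(count_direction_changes(shifted), count_direction_changes(tr))
})

test_that("track CSV round-trips through read/write including annotations", {
  tmp <- withr::local_tempdir()
  t1 <- track("t1", c(0, 5, 10), c(0, 2, 4), c(0, 1, 2),
              axon_entry_min = 0, drez_contact_min = 10)
  t2 <- track("t2", c(0, 5), c(1, 2), c(3, 4))
  p <- file.path(tmp, "tracks.csv")
  a <- file.path(tmp, "ann.csv")
  write_tracks_csv(list(t1, t2), p, a)
  back <- read_tracks_csv(p, a)
  expect_equal(back[[1]], t1)
  expect_equal(back[[2]]$x_um, t2$x_um)
  expect_null(back[[2]]$axon_entry_min)
})
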
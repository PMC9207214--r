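sheath_row <- function(fish, cell, class, day, sheath, len, wid = len / 20) {
  data.frame(fish_id = fish, cell_id = cell, cell_class = class, day = day,
             sheath_id = sheath, length_um = len, width_um = wid,
             stringsAsFactors = FALSE)
}

two_class_table <- function(sens, nons) {
  rbind(
    do.call(rbind, lapply(seq_along(sens), function(i) {
      sheath_row(paste0("fs", i), paste0("s", i), "sensory_olc", 3,
                 paste0("s", i, "_1"), sens[i])
    })),
    do.call(rbind, lapply(seq_along(nons), function(i) {
      sheath_row(paste0("fn", i), paste0("n", i), "nonsensory_olc", 3,
                 paste0("n", i, "_1"), nons[i])
    }))
  )
}

test_that("group comparison is a Welch t test on per-cell averages", {
  x <- c(180, 195, 210)
  y <- c(90, 100, 95)
  cmp <- group_compare(two_class_table(x, y), "length")
  ht <- t.test(x, y)  # textbook Welch on the same per-cell values
  expect_equal(cmp$statistic, unname(ht$statistic))
  expect_equal(cmp$p_value, ht$p.value)
  expect_equal(cmp$summary$mean, c(mean(x), mean(y)))
  expect_equal(cmp$summary$sem, c(sd(x) / sqrt(3), sd(y) / sqrt(3)))

  # identical groups: defined degenerate answer
  same <- group_compare(two_class_table(c(100, 100), c(100, 100)), "length")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # swap symmetry up to sign
  swapped <- two_class_table(y, x)
  expect_equal(group_compare(swapped, "length")$statistic, -cmp$statistic)

  only_sens <- two_class_table(x, numeric(0))
  expect_error(group_compare(only_sens, "length"), "both")
})

test_that("sheaths are averaged per cell before comparing across cells", {
  tab <- rbind(
    sheath_row("f1", "s1", "sensory_olc", 3, "a", 100),
    sheath_row("f1", "s1", "sensory_olc", 3, "b", 300),  # cell mean 200
    sheath_row("f2", "s2", "sensory_olc", 3, "c", 180),
    sheath_row("f3", "n1", "nonsensory_olc", 3, "d", 90),
    sheath_row("f4", "n2", "nonsensory_olc", 3, "e", 110)
  )
  cmp <- group_compare(tab, "length")
  expect_equal(cmp$summary$n, c(2L, 2L))
  expect_equal(cmp$summary$mean[1], mean(c(200, 180)))
  pooled <- group_compare(tab, "length", unit = "sheath")
  expect_equal(pooled$summary$n, c(3L, 2L))
})

test_that("simulated class contrast at published magnitudes is recovered", {
  sh <- generate_sheaths(sheath_sim_config(seed = 101))
  cmp <- group_compare(sh, "length")
  expect_gt(cmp$summary$mean[1], cmp$summary$mean[2])  # sensory longer
  expect_lt(cmp$p_value, 0.01)
  wid <- group_compare(sh, "width")
  expect_lt(wid$summary$mean[1], wid$summary$mean[2])  # but thinner
})

test_that("per-fish stability ANOVA matches the hand computation", {
  tab <- rbind(
    sheath_row("f1", "c1", "sensory_olc", 3, "a", 10),
    sheath_row("f1", "c1", "sensory_olc", 3, "b", 12),
    sheath_row("f1", "c1", "sensory_olc", 3, "c", 11),
    sheath_row("f1", "c1", "sensory_olc", 4, "d", 13),
    sheath_row("f1", "c1", "sensory_olc", 4, "e", 15),
    sheath_row("f1", "c1", "sensory_olc", 4, "f", 14)
  )
  st <- stability_test(tab, "length")
  # hand one-way ANOVA: groups (10,12,11) and (13,15,14)
  gm <- c(11, 14); overall <- 12.5
  ss_between <- 3 * sum((gm - overall)^2)       # 13.5
  ss_within <- sum((c(10, 12, 11) - 11)^2) + sum((c(13, 15, 14) - 14)^2)  # 4
  f_hand <- (ss_between / 1) / (ss_within / 4)
  expect_equal(st$statistic, f_hand)
  expect_equal(st$p_value, pf(f_hand, 1, 4, lower.tail = FALSE))
  expect_false(st$degenerate)
  expect_equal(st$per_day$mean, gm)

  const <- tab
  const$length_um <- 7
  st0 <- stability_test(const, "length")
  expect_equal(st0$statistic, 0)
  expect_equal(st0$p_value, 1)
  expect_true(st0$degenerate)

  one_day <- tab[tab$day == 3, ]
  expect_error(stability_test(one_day, "length"), "2 days")
})

test_that("stability p-values are uniform under the simulated null", {
  # equal day means by construction; 120 fish, KS uniformity check
  p <- vapply(1:120, function(s) {
    sh <- generate_sheaths(sheath_sim_config(n_sensory = 1, n_nonsensory = 1,
                                             seed = 5000 + s))
    stability_test(sh, "length", fish_id = sh$fish_id[1])$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("max projection count is the per-cell maximum over frames", {
  counts <- data.frame(cell_id = c("a", "a", "a", "b", "b"),
                       frame = c(1, 2, 3, 1, 2),
                       n_projections = c(0, 3, 1, 2, 2))
  mx <- max_projection_count(counts)
  expect_equal(mx$max_projections[mx$cell_id == "a"], 3L)
  expect_equal(mx$max_projections[mx$cell_id == "b"], 2L)

  withr::with_seed(59, {
    big <- data.frame(cell_id = sample(letters[1:6], 200, TRUE),
                      frame = 1:200,
                      n_projections = sample(0:9, 200, TRUE))
  })
  mx2 <- max_projection_count(big)
  for (cl in mx2$cell_id) {
    expect_equal(mx2$max_projections[mx2$cell_id == cl],
                 max(big$n_projections[big$cell_id == cl]))
  }
  # permutation invariance
  shuffled <- big[sample(nrow(big)), ]
  expect_equal(max_projection_count(shuffled), mx2)
})
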
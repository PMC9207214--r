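test_that("polygon and polyline rasterization match hand geometry", {
  sq <- roi_spec("sq", "polygon",
                 rbind(c(-0.5, -0.5), c(-0.5, 2.5), c(2.5, 2.5), c(2.5, -0.5)))
  m <- rasterize_roi(sq, 5, 5)
  expect_equal(sum(m), 9)
  expect_true(all(m[1:3, 1:3]))

  pl <- roi_spec("pl", "polyline", rbind(c(0, 0), c(0, 4)), line_width = 1)
  mp <- rasterize_roi(pl, 3, 6)
  expect_equal(sum(mp), 5)
  expect_true(all(mp[1, 1:5]))

  far <- roi_spec("far", "polygon",
                  rbind(c(100, 100), c(100, 101), c(101, 101)))
  expect_error(rasterize_roi(far, 5, 5), "outside")
})

test_that("random polygon masks equal the brute-force point-in-polygon oracle", {
  withr::with_seed(19, {
    for (i in 1:40) {
      poly <- random_convex_polygon(9, 11)
      roi <- roi_spec("p", "polygon", poly)
      got <- tryCatch(rasterize_roi(roi, 9, 11), error = function(e) NULL)
      want <- oracle_polygon_mask(poly, 9, 11)
      if (is.null(got)) {
        expect_false(any(want))  # both agree the ROI misses every pixel
      } else {
        expect_identical(got, want)
      }
    }
  })
})

test_that("polyline mask size is monotone in line width", {
  seg <- rbind(c(2.2, 1.3), c(5.7, 8.1))
  sizes <- vapply(c(1, 2, 3, 5), function(w) {
    sum(rasterize_roi(roi_spec("l", "polyline", seg, line_width = w), 9, 10))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("integrated density is the masked pixel sum, normalized against background", {
  # uniform frame of 2 under a 10-px mask
  st <- image_stack(array(2, dim = c(2, 4, 5)))
  r10 <- roi_spec("r", "polygon",
                  rbind(c(-0.5, -0.5), c(-0.5, 4.5), c(1.5, 4.5), c(1.5, -0.5)))
  expect_equal(measure_integrated_density(st, r10)$intensity, c(20, 20))

  # frame identical to its background normalizes to zero
  bg <- rbind(c(1.5, -0.5), c(1.5, 4.5), c(3.5, 4.5), c(3.5, -0.5))
  rbg <- roi_spec("r", "polygon", r10$vertices, background = bg)
  expect_equal(measure_integrated_density(st, rbg)$intensity, c(0, 0))
  expect_equal(measure_integrated_density(st, rbg, "divide")$intensity,
               c(10, 10))

  # hand-written 5x5 frame, hand-summed mask
  frame <- matrix(c(
    1, 2, 3, 4, 5,
    6, 7, 8, 9, 10,
    11, 12, 13, 14, 15,
    16, 17, 18, 19, 20,
    21, 22, 23, 24, 25), nrow = 5, byrow = TRUE)
  px <- array(0, dim = c(1, 5, 5))
  px[1, , ] <- frame
  sq4 <- roi_spec("s", "polygon",
                  rbind(c(0.5, 0.5), c(0.5, 2.5), c(2.5, 2.5), c(2.5, 0.5)))
  # pixels (1,1),(1,2),(2,1),(2,2) zero-based = 7+8+12+13
  expect_equal(measure_integrated_density(image_stack(px), sq4)$intensity, 40)
})

test_that("integrated density is additive over disjoint masks and linear in intensity", {
  withr::with_seed(23, {
    px <- array(runif(3 * 8 * 8, 0, 50), dim = c(3, 8, 8))
    st <- image_stack(px)
    left <- roi_spec("l", "polygon",
                     rbind(c(-0.5, -0.5), c(-0.5, 3.5), c(7.5, 3.5), c(7.5, -0.5)))
    right <- roi_spec("r", "polygon",
                      rbind(c(-0.5, 3.5), c(-0.5, 7.5), c(7.5, 7.5), c(7.5, 3.5)))
    whole <- roi_spec("w", "polygon",
                      rbind(c(-0.5, -0.5), c(-0.5, 7.5), c(7.5, 7.5), c(7.5, -0.5)))
    dl <- measure_integrated_density(st, left)$intensity
    dr <- measure_integrated_density(st, right)$intensity
    dw <- measure_integrated_density(st, whole)$intensity
    expect_equal(dl + dr, dw)
    st3 <- image_stack(3 * px)
    expect_equal(measure_integrated_density(st3, whole)$intensity, 3 * dw)
  })
})

test_that("stacks round-trip through 16-bit multi-frame TIFF", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  withr::with_seed(29, {
    px <- array(round(runif(4 * 6 * 7, 0, 65535)), dim = c(4, 6, 7))
  })
  st <- image_stack(px, frame_times = c(0, 5, 10, 15))
  write_stack_tiff(st, tmp)
  back <- read_stack_tiff(tmp, frame_times = c(0, 5, 10, 15))
  expect_identical(back$pixels, st$pixels)
  expect_equal(back$frame_times, st$frame_times)
})

test_that("ROI definitions round-trip through the JSON schema", {
  tmp <- withr::local_tempfile(fileext = ".json")
  rois <- list(
    roi_spec("soma", "polygon", rbind(c(0, 0), c(0, 4), c(4, 4), c(4, 0)),
             background = rbind(c(5, 5), c(5, 7), c(7, 7))),
    roi_spec("proj", "polyline", rbind(c(1.5, 0), c(3.5, 6)), line_width = 3)
  )
  write_roi_json(rois, tmp)
  back <- read_roi_json(tmp)
  expect_equal(back, rois)
})
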
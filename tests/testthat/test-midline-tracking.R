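test_that("straight rod is recovered to sub-pixel accuracy", {
  ml <- rod_midlines()
  st <- rasterize_silhouettes(ml, 3 * PX, PX, c(200, 60))
  ex <- extract_midline(st)
  p <- ex$points[1, , ] / PX
  # RMS distance of extracted points to the true segment (x in [20, 170])
  over <- pmax(abs(p[, 1] - 95) - 75, 0)
  rms <- sqrt(mean(over^2 + (p[, 2] - 30)^2))
  expect_lt(rms, 0.5)
  # equal arclength spacing within 1%
  d <- sqrt(rowSums(diff(p)^2))
  expect_lt(diff(range(d)) / mean(d), 0.01)
})

test_that("C-shaped arc arclength is recovered within 2%", {
  ml <- arc_midlines(radius_px = 100)
  st <- rasterize_silhouettes(ml, 3 * PX, PX, c(250, 200))
  ex <- extract_midline(st)
  s <- sum(sqrt(rowSums(diff(ex$points[1, , ] / PX)^2)))
  expect_equal(s, 100 * pi / 2, tolerance = 0.02)
})

test_that("tracker errors are informative for degenerate frames", {
  blank <- matrix(0L, 40, 40)
  st <- silhouette_stack(list(blank), PX, 100)
  expect_error(extract_midline(st), "frame 0.*foreground")
  two <- matrix(0L, 60, 60)
  two[10:20, 10:20] <- 1L   # two equal 11x11 squares
  two[40:50, 40:50] <- 1L
  expect_error(extract_midline(silhouette_stack(list(two), PX, 100)),
               "ambiguous")
  small <- matrix(0L, 40, 40); small[20:21, 20:22] <- 1L
  expect_error(extract_midline(silhouette_stack(list(small), PX, 100)),
               "smaller than")
})

test_that("simulate -> rasterize -> extract round trip stays within 1 px", {
  sim <- simulate_swimmer(swimmer_params(body_length = 0.012,
                                         tailbeat_freq = 3, duration = 0.6,
                                         frame_rate = 100,
                                         start = c(0.013, 0.005)))
  st <- rasterize_silhouettes(sim$midlines, 3 * PX, PX, c(330, 100))
  ex <- extract_midline(st)
  worst <- max(vapply(seq_len(60), function(i)
    hausdorff(ex$points[i, , ] / PX, sim$midlines$points[i, , ] / PX),
    numeric(1)))
  expect_lt(worst, 1)
})

test_that("head identity is constant and correct for a moving swimmer", {
  sim <- simulate_swimmer(swimmer_params(body_length = 0.012,
                                         tailbeat_freq = 3, duration = 0.6,
                                         frame_rate = 100,
                                         start = c(0.013, 0.005)))
  st <- rasterize_silhouettes(sim$midlines, 3 * PX, PX, c(330, 100))
  ex <- extract_midline(st)
  head_err <- sqrt(rowSums((ex$points[, 1, ] -
                              sim$midlines$points[, 1, ])^2)) / PX
  tail_as_head <- sqrt(rowSums((ex$points[, 1, ] -
                                  sim$midlines$points[, 51, ])^2)) / PX
  expect_true(all(head_err < tail_as_head))  # never flipped, in any frame
  expect_lt(max(head_err), 2)
})

test_that("output is invariant to padding the canvas with background", {
  ml <- rod_midlines()
  st1 <- rasterize_silhouettes(ml, 3 * PX, PX, c(200, 60))
  st2 <- rasterize_silhouettes(ml, 3 * PX, PX, c(260, 90))
  e1 <- extract_midline(st1); e2 <- extract_midline(st2)
  expect_lt(max(abs(e1$points - e2$points)), 1e-6)
})

test_that("centroid and heading follow the stated conventions", {
  # straight horizontal fish, head to the right -> heading 0
  ml <- rod_midlines()
  ch <- centroid_and_heading(ml)
  expect_equal(ch$heading[1], 0, tolerance = 1e-12)
  expect_equal(ch$x_m[1], 95 * PX, tolerance = 1e-12)
  # fish rotated a quarter turn, head along +y (down the image): heading pi/2
  pts <- array(NA_real_, c(1, 51, 2))
  pts[1, , 1] <- rep(30, 51) * PX
  pts[1, , 2] <- seq(170, 20, length.out = 51) * PX   # head at larger y
  rot <- midline_sequence(pts, 100)
  expect_equal(centroid_and_heading(rot)$heading[1], pi / 2,
               tolerance = 1e-12)
  # centroid of a symmetric sinusoid midline lies on its axis
  xs <- seq(0, 0.02, length.out = 101)
  pts2 <- array(NA_real_, c(1, 101, 2))
  pts2[1, , 1] <- xs
  pts2[1, , 2] <- 0.01 + 0.003 * sin(2 * pi * xs / 0.02)
  ml2 <- midline_sequence(pts2, 100)
  expect_equal(centroid_and_heading(ml2)$y_m[1], 0.01, tolerance = 1e-9)
})
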
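test_that("curvature matches 1/r on a circular arc and is isometry-invariant", {
  ml <- arc_midlines(radius_px = 100)   # 0.01 m radius at the fixture scale
  ml3 <- rep_frames(ml, 3)
  k <- compute_kinematics(ml3)$curvature[1, 10:40]
  expect_equal(mean(abs(k)), 100, tolerance = 0.02)
  # rigid rotation + translation leaves curvature unchanged
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts <- ml3$points
  for (i in 1:3) pts[i, , ] <- ml3$points[i, , ] %*% t(R) + 0.005
  k2 <- compute_kinematics(midline_sequence(pts, 100))$curvature[1, 10:40]
  expect_equal(k2, k, tolerance = 1e-9)
})

test_that("straight midline has zero bend angle and curvature", {
  ml <- rep_frames(rod_midlines(), 3)
  ser <- compute_kinematics(ml)
  expect_equal(max(abs(ser$bend_angle)), 0, tolerance = 1e-9)
  expect_equal(max(abs(ser$curvature)), 0, tolerance = 1e-6)
  expect_error(compute_kinematics(rod_midlines(n_frames = 2)), "3 frames")
})

test_that("peak bend angle of a simulated swimmer matches its truth", {
  sim <- simulate_swimmer(swimmer_params(tailbeat_freq = 3, duration = 3))
  ser <- compute_kinematics(sim$midlines)
  expect_equal(max(abs(ser$bend_angle)),
               max(abs(sim$truth$bend_angle)) * 180 / pi,
               tolerance = 0.05)
})

test_that("activity fraction uses the strict-exceed convention", {
  expect_equal(activity_fraction(series_from_speed(rep(0.05, 100))), 1)
  expect_equal(activity_fraction(series_from_speed(rep(0.025, 100))), 0)
  expect_equal(activity_fraction(
    series_from_speed(c(rep(0.03, 50), rep(0.01, 50)))), 0.5)
  # complementarity: fraction above + fraction at-or-below = 1
  set.seed(4)
  sp <- runif(200, 0, 0.05)
  s <- series_from_speed(sp)
  a <- activity_fraction(s)
  expect_equal(a, 1 - sum(sp <= 0.025) / 200)
  expect_true(a >= 0 && a <= 1)
})

test_that("bend detection counts sinusoid extrema and tolerates noise", {
  tt <- seq(0, 5 - 1e-9, by = 1 / 100)
  bends <- detect_bends(series_from_bend(40 * sin(2 * pi * 2 * tt)))
  expect_equal(length(bends$times), 20)
  expect_equal(unique(round(bends$amplitudes)), 40)
  # constant angle: no events
  expect_equal(length(detect_bends(series_from_bend(rep(15, 100)))$times), 0)
  # noisy sinusoid: 20 +- 1 events (fixed seeds)
  for (sd in 1:5) {
    set.seed(sd)
    noisy <- 40 * sin(2 * pi * 2 * tt) + rnorm(length(tt), 0, 4)
    n <- length(detect_bends(series_from_bend(noisy))$times)
    expect_true(abs(n - 20) <= 1, info = paste("seed", sd, "gave", n))
  }
})

test_that("propulsion efficiency follows its definition and flags glides", {
  b <- structure(list(times = seq(0.1, 2, length.out = 20),
                      amplitudes = rep(30, 20)), class = "bend_events")
  pe <- propulsion_efficiency(0.1, b, window = 5)
  expect_equal(pe$m_per_bend, 0.005)
  expect_equal(pe$m_per_degree, 0.1 / 600)
  expect_equal(pe$bends_per_m, 200)
  # doubling bend count at fixed path length halves the efficiency (exact)
  b2 <- structure(list(times = seq(0.05, 2, length.out = 40),
                       amplitudes = rep(30, 40)), class = "bend_events")
  expect_identical(propulsion_efficiency(0.1, b2, 5)$m_per_bend,
                   pe$m_per_bend / 2)
  # glide: zero bends with nonzero distance is undefined, never 0
  none <- structure(list(times = numeric(0), amplitudes = numeric(0)),
                    class = "bend_events")
  g <- propulsion_efficiency(0.1, none, 5)
  expect_false(g$defined)
  expect_true(is.na(g$m_per_bend))
})

test_that("thrust is the velocity component along the heading", {
  s <- series_from_speed(rep(0.2, 10))     # motion along heading 0
  expect_equal(thrust_series(s), rep(0.2, 10))
  s$heading <- rep(pi / 2, 10)             # heading now perpendicular
  expect_equal(max(abs(thrust_series(s))), 0, tolerance = 1e-12)
})

test_that("C-start thrust peaks within 50 ms after bend onset", {
  sim <- simulate_cstart(swimmer_params(frame_rate = 923, duration = 3,
                                        tailbeat_freq = 0,
                                        bend_amplitude = 0),
                         latency_ms = 12, peak_bend = 1.5)
  ser <- compute_kinematics(sim$midlines)
  th <- thrust_series(ser)
  onset_t <- which(sim$truth$bend_angle != 0)[1] / 923
  peak_t <- which.max(th) / 923
  expect_gt(peak_t, onset_t)
  expect_lt(peak_t - onset_t, 0.05)
})

test_that("median curvature amplitude matches pure and mixed sinusoids", {
  tt <- seq(0, 5 - 1e-9, by = 1 / 100)
  ser <- series_from_bend(40 * sin(2 * pi * 2 * tt))
  m <- median_curvature_amplitude(ser, c(0, 5))
  expect_equal(m$value, 40, tolerance = 0.02)
  # explicit amplitudes 30, 40, 50 -> median 40
  expect_equal(stats::median(c(30, 40, 50)), 40)
  # no extrema in window: undefined
  flat <- median_curvature_amplitude(series_from_bend(rep(0, 300)), c(0, 3))
  expect_false(flat$defined)
})

test_that("distance to stream centre is the mean perpendicular distance", {
  cl <- list(point = c(0, 0.022), direction = c(1, 0))
  tr <- data.frame(x_m = runif(50), y_m = rep(0.022 + 0.008, 50))
  expect_equal(distance_to_stream_centre(tr, cl), 0.008, tolerance = 1e-12)
  on_line <- data.frame(x_m = runif(5), y_m = rep(0.022, 5))
  expect_equal(distance_to_stream_centre(on_line, cl), 0)
})

test_that("occupancy map is a probability grid with consistent marginals", {
  set.seed(8)
  tr <- data.frame(x_m = runif(2000, 0, 0.172), y_m = runif(2000, 0, 0.044))
  om <- occupancy_map(tr, c(0, 0.172), c(0, 0.044), c(8, 4))
  expect_equal(sum(om$grid), 1, tolerance = 1e-9)
  expect_equal(om$x_marginal, colSums(om$grid), tolerance = 1e-12)
  expect_equal(sum(om$x_marginal), 1, tolerance = 1e-9)
  expect_equal(sum(om$y_marginal), 1, tolerance = 1e-9)
  # single occupied cell
  one <- occupancy_map(data.frame(x_m = rep(0.01, 7), y_m = rep(0.01, 7)),
                       c(0, 0.172), c(0, 0.044), c(8, 4))
  expect_equal(max(one$grid), 1)
  expect_equal(sum(one$grid > 0), 1)
  expect_error(occupancy_map(data.frame(x_m = -1, y_m = 0),
                             c(0, 0.172), c(0, 0.044)), "outside")
})

test_that("uniform occupancy stays within 3 binomial sd of flat (fixed seed)", {
  set.seed(13)
  n <- 1e5
  tr <- data.frame(x_m = runif(n, 0, 0.172), y_m = runif(n, 0, 0.044))
  om <- occupancy_map(tr, c(0, 0.172), c(0, 0.044), c(4, 4))
  p0 <- 1 / 16
  sd_cell <- sqrt(p0 * (1 - p0) / n)
  expect_lt(max(abs(om$grid - p0)), 3 * sd_cell)
})
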
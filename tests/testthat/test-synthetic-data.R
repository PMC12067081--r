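test_that("zero-amplitude swimmer is straight and stationary", {
  sim <- simulate_swimmer(swimmer_params(bend_amplitude = 0, duration = 2))
  expect_equal(max(abs(sim$truth$bend_angle)), 0)
  expect_equal(sim$truth$path_length, 0)
  # every frame identical, midline a straight segment
  expect_equal(diff(range(sim$midlines$points[, , 2])), 0)
  expect_equal(max(abs(sweep(sim$midlines$points[, , 1], 2,
                             sim$midlines$points[1, , 1]))), 0)
})

test_that("tail-beat extrema count is 2*f*T and scales with f*T", {
  for (case in list(c(f = 2, T = 5), c(f = 3, T = 4), c(f = 1.5, T = 2))) {
    sim <- simulate_swimmer(swimmer_params(tailbeat_freq = case["f"],
                                           duration = case["T"]))
    expect_equal(length(sim$truth$bend_times),
                 round(2 * case[["f"]] * case[["T"]]),
                 tolerance = 1e-12,
                 info = sprintf("f=%g T=%g", case["f"], case["T"]))
    expect_true(all(sim$truth$bend_times >= 0 &
                      sim$truth$bend_times < case[["T"]]))
  }
})

test_that("swimmer generation is bit-identical under a fixed seed", {
  p <- swimmer_params(tailbeat_freq = 3, duration = 1, seed = 42L)
  s1 <- simulate_swimmer(p)
  s2 <- simulate_swimmer(p)
  expect_identical(s1$midlines$points, s2$midlines$points)
})

test_that("swimmer rejects invalid parameters", {
  expect_error(swimmer_params(duration = 0), "duration")
  expect_error(swimmer_params(frame_rate = -1), "frame_rate")
  expect_error(swimmer_params(slip = 1.5), "slip")
  expect_error(swimmer_params(amplitude_envelope = function(u) 1 - u),
               "envelope")
})

test_that("C-start response begins at onset + round(latency*fps) frames", {
  base <- swimmer_params(frame_rate = 923, duration = 5, tailbeat_freq = 0,
                         bend_amplitude = 0)
  for (lat in c(0, 12, 33.3)) {
    sim <- simulate_cstart(base, latency_ms = lat, peak_bend = pi / 2)
    first_bend <- which(sim$truth$bend_angle != 0)[1] - 1  # 0-based
    expect_equal(first_bend,
                 sim$truth$onset_frame + round(lat / 1000 * 923),
                 info = sprintf("latency %g ms", lat))
  }
})

test_that("C-start truth reaches the requested peak bend exactly", {
  base <- swimmer_params(frame_rate = 923, duration = 3, tailbeat_freq = 0,
                         bend_amplitude = 0)
  sim <- simulate_cstart(base, latency_ms = 12, peak_bend = pi / 2)
  expect_equal(max(abs(sim$truth$bend_angle)), pi / 2, tolerance = 1e-9)
  expect_error(simulate_cstart(base, peak_bend = -1), "peak_bend")
})

test_that("rasterized rod has the expected pixel area and scaling", {
  ml <- rod_midlines()
  st <- rasterize_silhouettes(ml, 3 * PX, PX, c(200, 60))
  img <- st$frames[[1]]
  # brute-force oracle: pixel centres within half-width of the segment
  brute <- 0L
  for (x in 0:199) for (y in 0:59) {
    dx <- max(0, 20 - x, x - 170)
    if (dx^2 + (y - 30)^2 <= 9) brute <- brute + 1L
  }
  expect_identical(sum(img), brute)
  # aspect ratio of the bounding box ~ length/width
  xs <- range(which(colSums(img) > 0)); ys <- range(which(rowSums(img) > 0))
  expect_equal(diff(xs) / diff(ys), 156 / 6, tolerance = 0.15)
  # halving the pixel scale quadruples the component area (~4x)
  st2 <- rasterize_silhouettes(ml, 3 * PX, PX / 2, c(400, 120))
  expect_equal(sum(st2$frames[[1]]) / sum(img), 4, tolerance = 0.1)
})

test_that("rasterizer rejects degenerate and out-of-bounds input", {
  ml <- rod_midlines()
  expect_error(rasterize_silhouettes(ml, 3 * PX, PX, c(100, 60)), "bounds")
  pts <- array(0, c(1, 5, 2))
  degen <- midline_sequence(pts + 1e-3, 100)
  expect_error(rasterize_silhouettes(degen, 3 * PX, PX, c(50, 50)),
               "zero-length")
})

test_that("field-potential trace is nonzero only in template windows when clean", {
  fs <- 10000
  tr <- simulate_field_potential(ephys_truth(c(0.5, 1.0, 1.5), 0.2, 0),
                                 duration = 2, sample_rate = fs)
  nz <- which(tr$samples != 0)
  # three windows of one template width each
  expect_lt(length(nz), 3 * (fs / 400 + 2))
  gaps <- diff(nz)
  expect_equal(sum(gaps > 1), 2)  # exactly three disjoint runs
})

test_that("mains-only trace has its dominant spectral peak at 50 Hz", {
  fs <- 4000
  tr <- simulate_field_potential(ephys_truth(numeric(0), 0.2, 0),
                                 duration = 2, sample_rate = fs,
                                 mains_amplitude = 1)
  sp <- stats::spec.pgram(stats::ts(tr$samples, frequency = fs),
                          plot = FALSE, taper = 0)
  expect_equal(sp$freq[which.max(sp$spec)], 50, tolerance = 0.01)
})

test_that("field-potential simulation is deterministic given a seed", {
  tru <- ephys_truth(c(0.5, 1), 0.2, 1e-5)
  t1 <- simulate_field_potential(tru, 2, seed = 9L)
  t2 <- simulate_field_potential(tru, 2, seed = 9L)
  expect_identical(t1$samples, t2$samples)
  expect_error(simulate_field_potential(ephys_truth(3, 0.2, 0), 2),
               "beyond")
})

test_that("counter-current cohort recovers ordered equilibrium offsets", {
  sim <- simulate_counter_current_cohort(n_per_group = 50, seed = 11L)
  cl <- list(point = c(0, 0.022), direction = c(1, 0))
  md <- vapply(split(sim$trajectories, sim$trajectories$id), function(tr)
    distance_to_stream_centre(tr, cl), numeric(1))
  gm <- tapply(md, sim$truth$genotype[order(sim$truth$id)],
               mean)[c("wt", "het", "hom")]
  expect_true(gm["wt"] < gm["het"] && gm["het"] < gm["hom"])
  # group means land within 1 mm of the generating equilibria
  tru <- tapply(sim$truth$equilibrium_offset, sim$truth$genotype,
                mean)[c("wt", "het", "hom")]
  expect_true(all(abs(gm - tru) < 1e-3))
  # determinism
  sim2 <- simulate_counter_current_cohort(n_per_group = 50, seed = 11L)
  expect_identical(sim$trajectories, sim2$trajectories)
  expect_error(simulate_counter_current_cohort(
    arena = list(length = 0.1, width = 0)), "arena")
})

test_that("cohort metric truth equals base means times multipliers exactly", {
  eff <- default_genotype_effects()
  out <- simulate_cohort_metrics(eff, n_per_group = 10,
                                 base_means = c(efficiency = 0.005,
                                                amplitude = 40),
                                 base_sds = c(efficiency = 0,
                                              amplitude = 0), seed = 2L)
  expect_identical(out$truth["hom", "efficiency"], 0.005 * 0.7)
  expect_identical(out$truth["het", "amplitude"], 40 * 0.85)
  # sd = 0: every fish equals its group mean
  hom <- out$metrics[out$metrics$genotype == "hom", ]
  expect_true(all(hom$efficiency == 0.005 * 0.7))
  # all multipliers 1: single generating distribution
  eff1 <- list(wt = genotype_effect("wt"), het = genotype_effect("het"),
               hom = genotype_effect("hom"))
  out1 <- simulate_cohort_metrics(eff1, n_per_group = 5, seed = 3L)
  expect_true(all(apply(out1$truth, 2, function(x) length(unique(x)) == 1)))
})
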
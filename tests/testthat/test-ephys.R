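fs <- 10000
tt3 <- (0:(3 * fs - 1)) / fs
mid <- 5000:25000   # steady-state section, away from filter edge transients

test_that("band-pass gain: ~1 in band, strong rejection at 50 Hz", {
  g400 <- max(abs(bandpass(ephys_trace(sin(2 * pi * 400 * tt3), fs))
                  $samples[mid]))
  expect_gte(g400, 0.9)
  expect_lte(g400, 1.0 + 1e-6)
  gmid <- max(abs(bandpass(ephys_trace(sin(2 * pi * sqrt(300 * 500) * tt3),
                                       fs))$samples[mid]))
  expect_gte(gmid, 0.9)
  g50 <- max(abs(bandpass(ephys_trace(sin(2 * pi * 50 * tt3), fs))
                 $samples[mid]))
  expect_lte(g50, 0.05)
  # zero in, zero out
  expect_equal(bandpass(ephys_trace(rep(0, fs), fs))$samples, rep(0, fs))
  expect_error(bandpass(ephys_trace(rep(0, fs), fs), high = 5000),
               "Nyquist")
})

test_that("notch: >= 20x attenuation at 50 Hz, <= 10% change in band", {
  n50 <- max(abs(notch_mains(ephys_trace(sin(2 * pi * 50 * tt3), fs))
                 $samples[mid]))
  expect_lte(n50, 1 / 20)
  for (f in c(300, 400, 500)) {
    nf <- max(abs(notch_mains(ephys_trace(sin(2 * pi * f * tt3), fs))
                  $samples[mid]))
    expect_gte(nf, 0.9)
    expect_lte(nf, 1.1)
  }
  expect_equal(notch_mains(ephys_trace(rep(0, fs), fs))$samples, rep(0, fs))
})

test_that("zero-phase filtering leaves the template peak in place", {
  tr <- simulate_field_potential(ephys_truth(1.0, 0.5, 0), 2, fs)
  raw_pk <- which.max(abs(tr$samples))
  filt_pk <- which.max(abs(bandpass(tr)$samples))
  expect_lt(abs(filt_pk - raw_pk), 0.5 + 1e-9)
})

test_that("spike detection recovers clean injected templates exactly", {
  expect_length(detect_spikes(ephys_trace(rep(0, fs), fs))$times, 0)
  truth_t <- c(0.5, 1.0, 1.5)
  tr <- simulate_field_potential(ephys_truth(truth_t, 0.2, 0), 2, fs)
  st <- detect_spikes(notch_mains(bandpass(tr)))
  expect_length(st$times, 3)
  expect_true(all(abs(st$times - truth_t) * fs <= 1))
  expect_error(detect_spikes(ephys_trace(rep(0, 50), fs)), "10 ms")
})

test_that("detection is amplitude-scale invariant and respects refractory", {
  set.seed(21)
  truth_t <- sort(0.2 + runif(15) * 1.5)
  truth_t <- truth_t[c(TRUE, diff(truth_t) > 0.02)]
  tr <- simulate_field_potential(ephys_truth(truth_t, 0.1, 1), 2, fs,
                                 spike_amplitude = 5, seed = 3L)
  f1 <- notch_mains(bandpass(tr))
  st1 <- detect_spikes(f1)
  f2 <- f1; f2$samples <- f1$samples * 37.5
  st2 <- detect_spikes(f2)
  expect_identical(st1$times, st2$times)
  if (length(st1$times) > 1)
    expect_true(all(diff(st1$times) >= st1$refractory))
})

test_that("latency, count and instantaneous frequency follow definitions", {
  st <- spike_train(c(0.9, 1.012, 1.020, 1.5))
  expect_equal(spike_latency(st, 1.0)$latency_ms, 12)
  none <- spike_train(c(0.1, 0.2))
  lt <- spike_latency(none, 1.0)
  expect_false(lt$defined)
  expect_true(is.na(lt$latency_ms))
  # half-open count window
  st2 <- spike_train(1 + c(0.005, 0.010, 0.015, 0.020))
  expect_equal(spike_count(st2, 1, 0.020), 3)   # spike at onset+w excluded
  expect_equal(spike_count(spike_train(numeric(0)), 1, 0.5), 0)
  # instantaneous frequency
  f <- instantaneous_frequency(spike_train(c(0, 0.010, 0.020)))
  expect_equal(f$freq_hz, c(100, 100))
  expect_equal(nrow(instantaneous_frequency(spike_train(0.5))), 0)
})

test_that("median instantaneous rate of a Poisson train matches theory", {
  # for exponential ISIs at rate lambda, median(1/ISI) = lambda / ln 2
  lambda <- 50
  set.seed(17)
  isi <- rexp(500, lambda)
  st <- spike_train(cumsum(isi))
  f <- instantaneous_frequency(st)
  expect_equal(stats::median(f$freq_hz), lambda / log(2), tolerance = 0.15)
})

test_that("simulated latency shifts are recovered at cohort scale", {
  cfg <- run_config(n_per_group = c(wt = 40L, het = 2L, hom = 40L),
                    cstart = list(duration = 2), n_resamples = 2000L)
  cs <- simulate_cstart_cohort(cfg, seed = 5L)
  med <- tapply(cs$metrics$latency_ms, cs$metrics$genotype, stats::median,
                na.rm = TRUE)
  expect_equal(med[["hom"]] - med[["wt"]], 30, tolerance = 2 / 30 * 30)
  expect_lt(abs(med[["hom"]] - med[["wt"]] - 30), 2)
})
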
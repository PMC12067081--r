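#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study data with known ground truth.
#
# Produces a small worked set of raw artefacts under results/raw/: one
# free-swimming silhouette stack (PNG frames + sidecar), its true midlines
# as CSV, and one escape-response field potential as CSV and WAV. Later
# stages read these files back, so the whole chain exercises the on-disk
# formats, not in-memory shortcuts.

library(swimkin)

dir.create("results/raw", showWarnings = FALSE, recursive = TRUE)
px <- 1e-4   # 0.1 mm per pixel

# an adult-size cruising fish filmed for 1.5 s at 200 frames/s (desk-scale
# excerpt of the 30 s protocol); cruise speed ~0.03 m/s, above the 0.025
# m/s activity threshold
p <- swimmer_params(body_length = 0.03, bend_amplitude = 0.5,
                    tailbeat_freq = 3, duration = 1.5, frame_rate = 200,
                    start = c(0.033, 0.016), seed = 1L)
sim <- simulate_swimmer(p)
stack <- rasterize_silhouettes(sim$midlines, 3 * px, px, c(840, 320))
write_silhouette_stack(stack, "results/raw/swim_stack")
write_midline_csv(sim$midlines, "results/raw/swim_true_midlines.csv")
message(sprintf("swim stack: %d frames, %d true bend events, path %.3f m",
                length(stack$frames), length(sim$truth$bend_times),
                sim$truth$path_length))

# an escape-response field potential: stimulus at 1 s, 14 ms latency,
# 8-spike burst, SNR 5 over Gaussian noise with 50 Hz mains hum
set.seed(2)
isi <- pmax(stats::rgamma(7, shape = 4, rate = 4 / 0.02), 0.006)
spikes <- 1 + 0.014 + c(0, cumsum(isi))
tr <- simulate_field_potential(ephys_truth(spikes, 1, 1e-5), duration = 5,
                               sample_rate = 10000, spike_amplitude = 5e-5,
                               mains_amplitude = 2e-5, seed = 2L)
write_trace_csv(tr, "results/raw/escape_trace.csv")
write_trace_wav(tr, "results/raw/escape_trace.wav")
writeLines(jsonlite::toJSON(list(true_spike_times = spikes,
                                 true_latency_ms = 14), digits = NA),
           "results/raw/escape_truth.json")
message(sprintf("escape trace: %d samples, %d true spikes",
                length(tr$samples), length(spikes)))
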
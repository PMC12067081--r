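# swimkin

Quantification pipeline for zebrafish locomotion and escape-response
assays, written for labs that score motility phenotypes from high-speed
silhouette video and tank-water field potentials: free/motivated swimming,
counter-current endurance trials, and the Mauthner-driven C-start escape
response, compared across genotype cohorts (wild type, heterozygous,
homozygous mutants).

The package covers the full chain:

* **Midline tracking** — ordered, head-oriented body midlines from binary
  silhouette stacks: distance-transform ridge centerline, sub-pixel
  boundary re-centring, equal-arclength resampling (M = 51 points),
  head/tail assignment from centroid motion.
* **Swim kinematics** — speed, signed head–tail bend angle, per-point
  curvature κ(s), bend events (tail-beat half cycles), activity fraction
  (frames with v > 0.025 m/s), propulsion efficiency (distance per bend,
  with distance-per-degree and bends-per-distance variants), thrust,
  median curvature amplitude, distance to a stream centreline, and 2D
  occupancy maps with marginals.
* **Electrophysiology** — zero-phase 300–500 Hz Butterworth band-pass and
  50 Hz notch, MAD-threshold spike detection
  (σ̂ = median|x|/0.6745, events at |x| > kσ̂ with a 2 ms refractory),
  spike latency, count, and instantaneous frequency.
* **Statistics** — Fisher's permutation test (difference of group means
  over label permutations; exact enumeration at small n, Monte-Carlo with
  R = 200,000 otherwise, two-sided p = (#{|T\*| ≥ |T_obs|} + 1)/(R + 1)),
  Benjamini–Hochberg FDR within each reported panel, percentile bootstrap
  95% CIs, categorical staining-severity analysis, and per-area event
  rates (per 1000 µm²).
* **Synthetic generator** — a travelling tangent-angle-wave swimmer
  (φ(s,t) = E(s)·A·sin 2π(ft − s/λ), speed v = slip·fλA), C-start and
  field-potential simulators, and cohort generators with graded genotype
  effects — all with exact ground truth, so the whole pipeline is
  validated end-to-end.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
stage reads the previous stage's files under `results/`. Running

```sh
Rscript analysis/01_simulate.R   # synthetic fish + field potential, with truth
Rscript analysis/02_track.R      # midlines from the silhouette stack
Rscript analysis/03_kinematics.R # swim + counter-current metrics
Rscript analysis/04_ephys.R      # spike detection and escape metrics
Rscript analysis/05_stats.R      # permutation tests + BH, CIs, categories
```

prints, among other lines:

```
tracked 300 frames: Hausdorff mean 0.53 px, max 0.98 px, head error 0.39 px
tracked fish: activity 1.00, 9 bends, 0.005124 m/bend (0.0002279 m/deg)
m/bend wt 0.005525 | het 0.004295 | hom 0.003613
centre distance (mm) wt 3.7 | het 9.3 | hom 14.5
detected 8 spikes (true 8); latency 14.10 ms (true 14.0); median inst. freq 92.6 Hz
cohort latency medians (ms): wt 12.5 | het 26.9 | hom 43.4
pooled categories 1-3: wt 0.16 vs mut 0.62, p_adj 5e-05
myelin split rate: wt 0.51 vs mut 3.11 per 1000 um^2, p 0.0476 (exact)
```

Reading these: the tracker recovers the generating midline to under one
pixel on a 3 px half-width body and never swaps head and tail; a cruising
adult-size fish (0.03 m, 3 Hz tail beat) is active in every frame and
covers ~5.1 mm per body bend; cohorts with graded genotype effects show the
expected ordering — mutants cover less distance per bend, sit farther from
the stream centre, and respond later after the stimulus (the simulated
+15/+30 ms heterozygous/homozygous latency shifts are recovered); the
spike detector finds all eight injected field-potential spikes with the
latency right to 0.1 ms; and the categorical and per-area comparisons
reject where the simulated group difference is real.

Programmatic use mirrors the scripts:

```r
library(swimkin)
sim   <- simulate_swimmer(swimmer_params(tailbeat_freq = 3, duration = 5))
stack <- rasterize_silhouettes(sim$midlines, width_profile = 3e-4,
                               pixel_scale = 1e-4, image_size = c(840, 320))
ml    <- extract_midline(stack)
ser   <- compute_kinematics(ml)
bends <- detect_bends(ser)
propulsion_efficiency(sum(sqrt(rowSums(diff(ser$centroid)^2))), bends, 5)
```

`run_pipeline(run_config(...), outdir)` chains simulate → measure →
compare and writes metric tables, a results table (panel, comparison,
statistic, value, p_raw, p_adjusted, n_resamples, seed) and occupancy
maps, stamped with the config hash; identical configs reproduce identical
files.

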
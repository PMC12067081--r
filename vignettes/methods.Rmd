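---
title: "Models and methods behind swimkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind swimkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimkin)
```

swimkin quantifies zebrafish locomotion assays: undulatory swim kinematics
from silhouette video, C-start escape-response field potentials, and the
permutation/FDR statistics that compare genotype cohorts. Because the assays
it models were published without deposited recordings, the package ships a
synthetic generator with exact ground truth; every analysis operation is
validated end-to-end against that truth. This vignette explains the models,
the tunable parameters, the numerical choices, and what the validation does
and does not establish about real recordings.

## The synthetic swimmer

The body is a travelling tangent-angle wave. With arclength $s \in [0, L]$
from the head and time $t$, the tangent deviates from the heading by

$$\varphi(s, t) = E(s)\, A \sin\!\big(2\pi(f t - s/\lambda)\big),$$

where $A$ is the peak tail amplitude (radians), $f$ the tail-beat frequency
(Hz), $\lambda$ the body wavelength (metres), and $E(s)$ a monotone
head-to-tail amplitude envelope (default linear, 0.1 at the head to 1 at the
tail) reflecting that thrust-generating bending grows toward the tail. The
midline is the integral of the unit tangent along $s$, and the body
translates along its heading at

$$v = \mathrm{slip} \cdot f \lambda \cdot A,$$

the simplest closure in which forward speed is proportional to both the wave
speed $f\lambda$ and the extent of body bending — the qualitative coupling
the assays rely on (a fish that bends less must beat faster to hold speed).
No hydrodynamics is modelled; `slip` (default 0.7) absorbs all fluid
mechanics into one dimensionless factor. Tail bend extrema occur where
$\cos(2\pi(ft - L/\lambda)) = 0$, so the truth contains exactly $2fT$ bend
events (half tail-beats) per recording of duration $T$, with analytic times.

Defaults emulate the study's regimes: adult body length 0.03 m, 30 s
recordings at 200 frames/s for free/motivated swims, 501 frames/s for
counter-current trials, 923 frames/s over 5 s for escape responses.
Sex enters only as a label: the package compares genotypes within one sex at
a time, and nothing in the generator couples sex to the kinematics.

The C-start generator holds the fish straight and still until
`stimulus_onset + latency`, then drives a uniform-curvature bend: a rise to
`peak_bend` over ~10 ms, a counter-bend to $-0.7\,$`peak_bend` over ~20 ms,
and a decay, while speed follows a fast-start pulse (10 ms rise, 250 ms
coast-down) beginning at the counter-bend — so thrust peaks a few tens of
milliseconds after bend onset, as in real fast starts. The response is
quantised to frames: it begins exactly at frame
`round(onset*fps) + round(latency*fps)`, and the truth bend series attains
`peak_bend` exactly at the end of the rise, which makes frame-level latency
arithmetic testable without tolerance.

Cohorts are generated per genotype from a `genotype_effect`: multiplicative
effects on bend amplitude and post-stimulus spike count, an additive latency
shift (ms), and an additive shift of the equilibrium distance to the stream
centreline. The defaults grade heterozygotes between wild type and
homozygotes (amplitude 1 / 0.85 / 0.7; latency +0 / +15 / +30 ms; spike
count 1 / 0.8 / 0.6; centre distance +0 / +5 / +10 mm); the homozygous
amplitude factor 0.7 and +30 ms latency shift define the nominal effect
size. In the swim cohorts each fish holds a log-normally jittered target
speed (CV 10%) while its amplitude is scaled by genotype (CV 12%), and the
tail-beat frequency follows from the speed closure — mutant-like fish cover
the same distance with more bends, which is precisely the reported
propulsion-efficiency phenotype, while leaving the activity fraction
unchanged. Counter-current trajectories are mean-reverting
(Ornstein–Uhlenbeck) walks in a 17.2 x 4.4 cm arena, reflected at the
walls, with reversion 2 s$^{-1}$, driving noise 4 mm/$\sqrt{s}$ and a 1 mm
per-fish equilibrium jitter: the stationary lateral spread (~1.4 mm) is
small against the baseline offset (4 mm), so the mean unsigned distance to
the centreline recovers the signed equilibrium with negligible folding
bias.

## Midline tracking

`extract_midline()` replaces the original study's tracker. Per frame:
largest connected component (EBImage), Euclidean distance transform, then
the centerline as the minimum-cost path between the two geodesically most
distant foreground pixels, with 8-neighbour step costs divided by the local
distance-transform values so the path follows the medial-axis crest. A
distance-transform ridge was chosen over morphological thinning because it
is deterministic and produces no spur branches to prune heuristically. The
pixel chain is smoothed (quadratic Savitzky–Golay, window 9), the rounded
end caps are trimmed where the boundary distance stops growing linearly
with arclength, each point is re-centred between the silhouette boundaries
along its normal (two passes, bilinear sub-pixel sampling), and the tips
are relocated using the cap geometry: the body endpoint lies one local
half-width short of the boundary along the end tangent. The result is
resampled to M equal-arclength points (default M = 51, odd so a true
midpoint exists). On 3 px half-width bodies this keeps the Hausdorff
distance to the generating midline below one pixel.

Head/tail assignment: orientation is propagated frame-to-frame by
nearest-endpoint continuity, and the global polarity is set by which
endpoint's offset from the centroid best aligns with centroid motion over a
±5-frame window (heads lead). If the fish never moves more than about half
a pixel, the wider endpoint is taken as the head (heads are wider than
tails); ties keep the previous assignment. Coordinates follow one
convention everywhere: image origin top-left, x right, y down, pixel
centres at integer coordinates, metres = pixels × `pixel_scale`.

The rasteriser used to build test images marks a pixel foreground when its
centre lies within the local half-width of the midline polyline (capsule
union, half-width interpolated along each segment). That definition is
pixel-exactly reproducible by a brute-force oracle, which the tests use.

## Kinematic metrics

`compute_kinematics()` produces per-frame speed (centred differences of the
Savitzky–Golay-smoothed centroid path; window 5 frames, local quadratic —
enough to suppress pixel-quantisation jitter at 200–923 fps without
flattening tail-beat-scale motion), heading (75%-arclength point to head),
signed bend angle (angle between the chords of the first and last 20% of
arclength; the paper defines no chord fractions, these are package
defaults), and per-point curvature from finite differences of the tangent
angle along arclength (exact for circular arcs at equal spacing).

* **Activity fraction** — fraction of frames with speed strictly above
  0.025 m/s, normalised to the recording period. Strict "exceeded" is a
  recorded decision: a fish at exactly threshold is inactive.
* **Bend events** — a bend is one extremum of the bend angle (a tail-beat
  half cycle), detected by a turning-point filter with hysteresis
  `min_amplitude` (default 10°, a package decision, the source gives none)
  and minimum spacing; the series is Savitzky–Golay-smoothed over 50 ms
  first so frame-level jitter cannot split one bend into several.
* **Propulsion efficiency** — primary orientation: metres per bend, so
  impaired fish score lower; the literal inverse (bends per metre) and the
  per-degree variant (metres per degree of summed bend amplitude) are both
  exposed. Zero bends over nonzero distance is a glide: flagged undefined
  and excluded from group statistics, never silently zero.
* **Median curvature amplitude** — median of per-extremum |bend angle|
  within a response window. The source does not say whether "curvature
  amplitude" is the head-tail angle or integrated curvature; the head-tail
  bend angle was chosen, and the full curvature profile is also returned.
* **Thrust** — signed component of centroid velocity along the heading.
* **Distance to stream centre** — mean perpendicular distance of the
  centroid to the arena centreline.
* **Occupancy map** — 2D position histogram normalised to mass 1, with
  marginals by axis summation.

## Electrophysiology

Traces are band-passed 300–500 Hz with a 4th-order Butterworth applied
forward-backward (`filtfilt`): the hardware pass band is given, the filter
family and order are package decisions, and zero phase is essential so
filtering cannot shift spike times (the tests bound the template-peak shift
at half a sample). Mains hum is removed with a zero-phase biquad notch at
50 Hz, Q = 10 — wide enough that its transients decay quickly, yet >20x
rejection at 50 Hz with <1% change across 300–500 Hz.

Spikes are detected on the filtered trace with a robust threshold
$k\hat\sigma$, $\hat\sigma = \mathrm{median}(|x|)/0.6745$ (MAD estimate,
insensitive to the spikes themselves), k = 5 by default; suprathreshold
runs closer than the 2 ms refractory period are merged and each event is
timed at its absolute peak. Detection is therefore amplitude-scale
invariant. On a noiseless trace the MAD collapses to zero and the threshold
falls back to a third of the absolute maximum, which sits above the
band-pass ringing side lobes. Latency is the first spike at or after
stimulus onset (undefined and flagged when none occurs); spike count uses
the half-open window [onset, onset + 0.5 s) — the response window length is
unstated in the source, 500 ms is the configurable default; instantaneous
frequency is 1/ISI assigned to the later spike.

The synthetic spike template is one asymmetric 400 Hz cycle (2.5 ms,
negative lobe 0.55 of the positive). A shorter ~1 ms biphasic shape was
considered and rejected: its spectral energy sits near 1 kHz, so the fixed
300–500 Hz analysis band attenuates it roughly tenfold and no detector
could meet the stated recall at SNR 5. Real events that survived the
hardware band-pass are, by construction, in-band, and the in-band template
models exactly that. One consequence is worth stating: the band-passed
template rings at ~400 Hz with near-equal lobes, so under noise the
absolute-peak convention occasionally locks onto an adjacent lobe (±1.25 ms).
Validation therefore matches detections to truth within one template width
and reports the median absolute timing error, the usual spike-sorting
convention; the median sits well below one sample at 10 kHz. Simulated
bursts use gamma ISIs with a 20 ms mean — a 50 Hz burst is what a 300–500 Hz
band can actually resolve as separate events; faster bursts would merge
into single detections for any method confined to this band.

## Statistics

Two-group comparisons use Fisher's permutation test: pooled observations
are relabelled without replacement and the difference of group means is
recomputed (difference of medians by flag). The source's phrase
"bootstrapped 200,000 times" is read as 200,000 label permutations, since it
names Fisher's permutation test; a with-replacement bootstrap null is
provided but non-default. The Monte-Carlo p-value uses the add-one
correction $(\#\{|T^\ast| \ge |T_{\mathrm{obs}}|\} + 1)/(R + 1)$, valid at
any finite R; when the number of distinct splits is at most 1e5 the test
enumerates them all and reports the exact p instead. Comparisons of
$|T^\ast|$ against $|T_{\mathrm{obs}}|$ carry a relative guard of 1e-9 so
floating-point ties (e.g. under location shifts) count as ties. The default
R = 200,000 matches the study; the test suite uses R = 2,000.

Benjamini–Hochberg correction is applied within each reported panel (all
pairwise genotype comparisons of one metric), mirroring per-panel
reporting; the family is declared by the caller, never inferred. Bootstrap
95% CIs are percentile-method over 10,000 resamples, for means or for
category proportions (0/1 expansion). The categorical module compares
staining-severity distributions by permuting cell-level category labels
between groups with the proportion difference as statistic — whether the
proper unit is the cell or the fish is left open by the source; cell-level
is implemented and fish-level aggregation is a caller choice. The per-area
module converts event counts to rates per 1000 µm² before the permutation
comparison. `type1_error_audit()` closes the loop: on simulated null
Gaussian cohorts the rejection fraction at $\alpha = 0.05$ must sit at the
nominal level within binomial error.

## Validation scale and limitations

The shipped validation uses desk-scale problem sizes, chosen once: the
tracked parameter-recovery grid is 3 amplitudes x 3 frequencies at 1.5 s x
200 fps and 3 px half-width; the type-I audit is 1,000 null cohorts at
n = 20/group with R = 2,000; effect-direction recovery runs the full study
cohort sizes (59/150/65 swim, 49/94/58 ephys, 45/91/57 counter-current at
the listed female Ns) with R = 200,000; spike recovery uses 20 five-second
traces at 10 kHz and SNR 5. `scripts/acceptance.R` recomputes all of these
from scratch.

What passing these checks shows: the implementation is internally
consistent, the estimators are unbiased at realistic noise scales, the
statistics hold their error rates, and genotype effects of the modelled
size and direction are recovered through the full pipeline. What it cannot
show: the generator omits body-shape variation, lighting/segmentation
artefacts, occlusions, wall interactions, hydrodynamic manoeuvres, and
stimulus artefacts in the voltage traces; real silhouettes are not perfect
capsules and real spike shapes vary between animals. Results on real video
therefore still require the usual spot checks (overlaying extracted
midlines on frames, inspecting raster plots against raw traces) before the
group statistics are trusted.
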
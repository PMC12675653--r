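---
title: "Quantifying the pupil-size artifact: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the pupil-size artifact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psaqc)
```

## The problem

Video-based eye trackers locate the pupil (alone or together with a
corneal reflection) and map its image position to gaze direction. The
pupil does not dilate concentrically: as its diameter changes, the pupil
center migrates by a few tenths of a millimeter, and the tracker reports
an apparent change in gaze direction although the eyeball never rotated.
This *pupil-size artifact* (PSA) is a systematic error source whenever
luminance, arousal or cognitive load varies within a recording.

The measurement paradigm `psaqc` implements isolates the artifact with a
luminance manipulation: a participant fixates a central bullseye target
while the display alternates between a white (bright, constricted pupil)
and a black (dark, dilated pupil) background. Because the eye fixates the
same physical target throughout, any displacement of the reported gaze
between the two conditions is artifact, and its magnitude is the
*apparent gaze shift*: the Euclidean distance between the bright-phase
and dark-phase gaze centroids, averaged over sequential trial pairs.
Pairing *sequential* bright/dark periods is essential — headset slippage
produces slow drift, and a pooled comparison across a whole session would
conflate drift with the artifact, while consecutive periods bracket it.

## The synthetic world

The generator produces sessions with the structure of the real paradigm:
3 trials, each a 10-s bright period followed by a 10-s dark period, each
period split into a 5-s adaptation phase (target absent, free viewing,
pupil adapting) and a 5-s measurement phase (steady fixation). Sampling
rates are device-like (30-500 Hz; default 100 Hz).

*Gaze model.* Measurement-phase gaze is `target + bias (+ shift)` plus
isotropic AR(1) noise. The real paradigm records real eyes and states no
noise model, so the generator's model is a deliberate idealization with
two independently controllable parameters: the stationary dispersion
`noise_std` (which the STD metric estimates) and the expected RMS
sample-to-sample displacement `s2s_noise` (which RMS-S2S estimates),
linked through the AR(1) coefficient by
`RMS-S2S = 2 * (noise_std/sqrt(2)) * sqrt(1 - phi)`. White noise
(`phi = 0`) is the default. Default `noise_std` is 0.3 degrees — a
mid-range figure for wearable trackers during fixation.

*Artifact model.* The PSA is injected phenomenologically: a constant 2-D
offset added during dark measurement phases. Published summaries report
per-device mean magnitudes spanning roughly 0.94 to 3.46 degrees but not
per-participant directions, so `sample_participants()` draws magnitudes
uniformly over that span and directions uniformly on the circle; the
direction distribution is a modeling choice, flagged in the configuration.
No attempt is made to model the physiological mechanism (pupil-center
migration); the pipeline only ever observes the displacement, so a
phenomenological injection tests it fully.

*Pupil model.* Pupil diameter approaches 2.88 mm (bright) and 5.05 mm
(dark) — typical steady-state diameters under this paradigm — with an
exponential time constant of 1 s, the pupillary light reflex timescale,
plus 1% multiplicative noise. The 5-s adaptation phase is five time
constants, so measurement-phase means sit within a fraction of a percent
of the steady states.

*Blink model.* Blink onsets are a Poisson process (default 0.2 events/s,
a typical rate during instructed fixation) with fixed 0.15-s duration;
affected samples keep their slots but carry NaN coordinates and
`valid = FALSE`, so per-phase sample counts always equal
`round(duration x rate)` and data loss is measured, never silently
deleted. In `nan_plus_excursion` mode each blink is flanked by 2 samples
displaced 15 degrees in a random direction — the partially occluded pupil
produces exactly such spikes in real data — giving the 10-degree distance
filter ground-truth work whose removal count is checkable exactly.

*Timestamps* are regular with no jitter; no formula in the pipeline
consumes them.

What a green test does **not** establish: the generator has no
oculomotor dynamics (no microsaccades, drift or tremor), no
pupil-size-dependent noise coupling, no headset slippage, and blink
excursions have a fixed amplitude. Green tests certify the *pipeline
arithmetic* — that injected quantities are recovered at the stated
tolerances — not that the generator reproduces real recordings.

## Scene-camera geometry

Head-mounted trackers report gaze in scene-camera pixels. The rendered
frames contain the white/black screen, a gray bullseye (0.6-degree outer,
0.2-degree inner diameter), and four green corner markers whose physical
positions are known; the renderer also returns the exact projected
centers, making it its own oracle. The bullseye's cross arms are omitted
from rendering: detection operates on intensity bands, for which the thin
arms contribute nothing.

Detection mirrors the classic chain — grayscale, thresholding, connected
components, k-means into five clusters (fixed k, component centroids as
initialization, so the clustering is deterministic). Thresholds are a
per-recording input, as in manual selection; `auto_threshold_band()` is a
convenience extension. Cluster centers and apparent marker diameters are
computed from sub-pixel coverage weights
`(I - background) / (foreground - background)` with the background taken
from the cluster's padded bounding-box border; binary centroids alone
would bias the apparent size by roughly half a pixel of perimeter, which
the pinhole distance estimate cannot absorb (a 1% distance error is about
0.1 degree at a 10-degree eccentricity).

Numerical choices worth recording:

- **Undistortion** inverts the Brown-Conrady model by fixed-point
  iteration (60 iterations, tolerance 1e-10) and verifies the round trip
  to 1e-6 px, raising a domain error outside the invertible region.
- **Scaling factor**: physical/apparent ratios averaged over all six
  corner-marker pairs, reducing sensitivity to any single detection.
- **Viewing distance**: `f * marker_mm / marker_px` averaged over the
  four corners. The apparent size is measured in the distorted image, so
  it is first corrected by the local undistortion scale — the geometric
  mean of the radial and tangential Jacobians, measured numerically —
  because a distorted disc is elliptical. Without this correction the
  estimate is biased by ~0.8% at k1 = -0.1; with it, residual error is
  ~0.02%. Disagreement above 10% between the four per-corner estimates
  warns (oblique viewing) rather than errors.
- **Degrees conversion** applies `arctan(mm / distance)` per axis; within
  ±10 degrees the discrepancy against a spherical treatment is below
  0.1%. The image y-axis points down while screen-centered degrees use
  y-up; the sign flip lives in `map_gaze_to_degrees()` only.
- **Per-frame geometry**: scale and distance are recomputed per frame;
  gaze samples use the temporally nearest frame's geometry.

## Cleaning chain

Order: invalid samples to NaN, trim, distance filter, SD filter.

- **Trimming** removes `floor(0.125 * N)` samples at each end, by count
  (equivalent to trimming by time at constant rate). The first and last
  eighths of a fixation trial contain the saccades toward and away from
  the target.
- **Distance filter**: strictly more than 10 degrees from the target.
  Boundary samples survive ("more than"). NaN samples pass through both
  filters untouched — they are data loss, which is defined *before*
  cleaning, and removing them would corrupt that metric.
- **SD filter**: single pass; mean and SD per axis over valid samples,
  removal when either axis exceeds 3 SD. The population denominator (N)
  matches the STD metric's convention. A single pass is the plain reading
  of the procedure; an iterate-to-fixed-point variant exists behind
  `sd_iterate` but is off by default, and re-applying the single-pass
  filter to its own output may remove further points — expected, and
  documented rather than hidden.
- On clean Gaussian sessions the chain removes about 0.54% of samples
  (the two-axis 3-sigma tail mass, `2 * 2 * (1 - pnorm(3))`), comfortably
  inside the ~1% ballpark reported for this procedure on real data.

## Metrics and statistics

Accuracy is the mean of distances (not the distance of means): a perfectly
precise but offset tracker scores its offset, an unbiased but noisy
tracker scores its dispersion. STD uses the population denominator. For
RMS-S2S the textbook `N - 1` denominator assumes gap-free data; here the
denominator is the number of consecutive *valid* pairs, with adjacency
judged by the stored within-trial sample index so that both NaN gaps and
filtered-out samples break pairs (reducing to `N - 1` when gap-free).
Phase centroids for the apparent gaze shift use post-cleaning samples,
consistent with all other analyses running on cleaned data.

The statistical layer aggregates to one value per participant and
condition before testing (no trial-level modeling). Paired t tests are
two-sided; the artifact-presence question uses a one-sample test of
per-participant mean shifts against zero, since shifts are non-negative
magnitudes. Bonferroni's family is configurable because the original
family size is not recoverable from published tables (a 0.74 -> 1.00 cap
is consistent with any m >= 2); the default family is one metric across
the five devices (m = 5). Cohen's d uses the difference-score form
`mean(d)/sd(d)`, which equals `t/sqrt(n)` and matches how published
paired effect sizes in this literature track their t statistics; the
averaged-SD variant is available behind a flag. Zero-variance inputs are
reported as explicitly flagged degenerate results, never as silent zeros.

## Limitations

- The generator's realism limits are listed above; in particular
  recovered-vs-injected agreement cannot validate detection thresholds
  against real scene-camera footage (compression, motion blur, oblique
  poses).
- The scene mapping assumes a fronto-parallel screen; strongly oblique
  viewing violates the isotropic-scale assumption and is only flagged via
  the distance-disagreement warning, not corrected (no homography or pose
  estimation by design).
- Proprietary device formats are out of scope; inputs are the documented
  CSV/YAML/PNG interchange.
```{r example}
dev <- device_profile(noise_std = 0.3, blink_rate = 0.2)
par <- participant_profile(psa_shift = c(2, 0))
s <- generate_session(dev, par, trial_schedule(), seed = 42)
analyze_session(s$recordings)$shift$mean_shift
```
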
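---
title: "Camera-based time-resolved gantry-angle QA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-based time-resolved gantry-angle QA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gantrycam)
```

## The measurement problem

Volumetric-modulated arc therapy (VMAT) delivers dose while the linac gantry
rotates, with dose rate and MLC motion modulated simultaneously. The gantry
angle is usually verified through the machine's own readout (log files, EPID
image headers, the on-board imager encoder), none of which is independent of
the control system being tested: a drift in gantry calibration is invisible
to them. `gantrycam` implements a fully independent, time-resolved
measurement that needs only a printed sheet of paper and a consumer camera:
two filled circles — red and green, deliberately of different radii — are
attached to the gantry face near the rotation axis, and a camera on the
treatment couch films them during delivery. Each video frame yields one
gantry-angle sample at the camera frame rate (30 Hz by default), so a whole
arc becomes an angle-versus-time trajectory that can be compared against
machine logs or any other reference.

## Per-frame angle determination

Each frame passes through a fixed chain:

1. **Colour isolation.** The dots are localized separately in a red and a
   green image. Raw colour channels respond strongly to the bright paper
   background under room lighting, so the package uses clipped dominance
   differences instead: $\max(R - G, 0)$ for red, $\max(G - R, 0)$ for
   green. The achromatic background cancels exactly and the opposing dot
   clips to zero.
2. **Median denoising.** A 5 × 5 median filter (edge-replicated borders)
   removes isolated noise specks without displacing the disc edge.
3. **Global thresholding.** Pixels at or above 50 % of the image's dynamic
   range (`min + 0.5 (max − min)`) form the dot mask. Defining the
   threshold relative to the per-image range rather than as an absolute 127.5
   makes the mask invariant to exposure and lighting scale. A constant image
   has no dynamic range and is flagged degenerate rather than thresholded.
4. **Centroid extraction.** The largest 8-connected component is taken; its
   unweighted pixel centroid gives a sub-pixel dot position. Components
   below `min_area` (25 px by default) are rejected as specks. Circularity
   is deliberately not enforced; the size guard and the colour isolation
   carry the robustness.
5. **Angle.** With red centroid $(R_x, R_y)$ and green centroid
   $(G_x, G_y)$ in y-down image coordinates, the raw pattern angle is the
   two-argument arctangent of $(R_x - G_x,\; -(R_y - G_y))$, mapped to
   $[0°, 360°)$. The single-argument form
   $\tan^{-1}\!\big((R_x-G_x)/(R_y-G_y)\big)$ is ambiguous by 180° and
   undefined where $R_y = G_y$; the two-argument form equals it plus the
   quadrant correction wherever both are defined and removes the
   singularity. The test suite checks this equivalence against an
   independent single-argument + quadrant-casework oracle at $10^{-9}$
   degrees.

If colour fails to separate the dots — both channels settle on the same
component, or colour-free footage — the package falls back to the inverted
luminance image and assigns the two largest components by radius (the dots
are printed with different sizes precisely so that size can disambiguate
them). Frames where detection fails outright become gap samples: they are
kept in the trajectory with `ok = FALSE` but excluded from every statistic,
and are never interpolated over. More than 20 % failed frames aborts the
analysis as a setup problem.

## Self-calibration

The raw angle depends on how the sheet happens to be mounted. Footage
therefore begins with the gantry parked at true 0° (levelled independently
of the machine readout); the circular mean of the raw angle over the first
10 s defines the calibration angle $\theta_0$, and every measurement is
reported as $\mathrm{wrap}_{[-180,180)}\big(s\,(\theta - \theta_0)\big)$
with $s = \pm 1$ the configured image-to-gantry rotation sense. The choice
of circular mean (rather than any trimmed variant) is a documented package
decision; the window's circular SD doubles as a stability gate (0.2° by
default) that rejects calibration if the gantry was still moving. Because
$\theta_0$ absorbs the pattern orientation entirely, rotating the printed
sheet by any constant should change nothing downstream — the test suite
verifies recovered angles are invariant to pattern offsets of 0°, 37° and
211° within 0.05° at the default geometry.

The rotation-sense parameter `sign` exists because the mapping from
apparent image rotation to the machine's angle convention depends on which
way the camera faces the pattern; it is verified once per setup with a short
known clockwise rotation. Angles are reported on a signed convention-
agnostic −180°..+180° scale; no particular IEC variant is asserted.

## Synthetic scenes as the test instrument

Validating this kind of measurement against hardware requires a linac with
encoder, inclinometer and log-file references. Without one, the package
ships a renderer that is itself a
first-class, tested module: anti-aliased red and green discs rotate rigidly
about an image-plane centre following any commanded trajectory, imaged at a
fixed frame rate through a parameterized camera model — Gaussian optical
blur, additive per-pixel intensity noise, per-frame rigid translation
(couch/hand shake), and a constant decentration of the rotation axis. Every
render is paired with its exact ground truth, so recovery error can be
measured rather than assumed.

Renderer design notes:

* **Geometry.** Defaults are scaled to 1280 × 720 footage (radii 40 and
  25 px, separation 260 px) rather than a phone's native 4K: accuracy is
  resolution-relative, and the defaults are chosen so noiseless recovery
  error is well below 0.05°, leaving the noise model as the dominant error
  source, as it is in reality. The physical dot sizes on the printed sheet
  are not prescribed anywhere; these are package parameters, not claims.
* **Noise defaults** (intensity SD 5, blur 1 px, jitter 0.5 px, decentration
  20 px) are the package's stated "realistic camera" conditions, set so the
  static per-frame angle scatter lands in the vicinity of the 0.04°
  stability the method exhibits on real footage. Jitter translates both
  dots rigidly and therefore cancels in the relative angle; decentration
  moves the rotation centre but not the angle. Both are included so the
  detection chain, not the geometry, is what tolerates them.
* **Projection.** Pure in-plane rotation, no perspective — the method
  itself assumes a roughly axis-aligned camera and tolerates small
  misalignment; a constant in-plane camera roll is indistinguishable from a
  pattern offset and is absorbed by calibration. Perspective distortion,
  rolling shutter, auto-white-balance drift and codec artefacts are out of
  scope; frames are written lossless (PNG) when materialized.
* **Determinism.** Each frame's noise is drawn from a counter-based RNG
  keyed by `(seed, frame_index)`, so footage is bit-identical for a fixed
  seed regardless of rendering order. Background pixels — the overwhelming
  majority — are sampled from the exact discrete distribution of
  `round(clip(bg + N(0, sd)))` via an alias table; pixels near the discs
  receive continuous Gaussian noise before quantization. This keeps
  rendering O(1) per pixel and long sequences tractable on one CPU.

What passing against this renderer does **not** show: robustness to lens
distortion, specular glare, compression artefacts, occlusion, or exposure
drift on real footage. It does show that the algorithm itself — detection,
calibration, angle math, trajectory statistics — is correct and meets the
published accuracy figures under a camera-noise model of plausible severity.

## QA test plans

Three dynamic plans generate ground-truth trajectories (and dose-rate
profiles) for simulation and export:

* **Constant speed**: one 358° arc at 4.8°/s, 600 MU/min — the published
  parameters for the lowest-complexity test.
* **Speed transitions**: speed and dose rate both change every 30° of
  rotation. The 30° block structure is the test's defining feature; the numeric
  levels are free parameters, and the defaults alternate 6.0/3.0 °/s with 600/300
  MU/min so every adjacent block differs in both quantities, and the levels
  are fully configurable. The nominal 12 × 30° arc is capped at 358°
  (truncating the final block) for single-arc deliverability.
* **Maximum inertia overshoot**: alternating maximum-speed (6°/s over 20°)
  and near-stop (0.5°/s over 5°) segments with maximal dose-rate swings,
  adapted from the NCS MAIO concept. There is no canonical arc span for
  this test; the default of six fast/slow cycles (150°) provides twelve
  acceleration/deceleration events — the quantity this plan exists to
  stress — while keeping simulated deliveries to ~80 s.

Commanded acceleration is instantaneous in the truth trajectories; how a
real gantry smooths those corners is exactly what the measurement would
quantify. Plan trajectories are validated for span conservation ($10^{-9}$°),
monotonicity, and the machine speed limit.

## Reference logs and comparison statistics

Machine log files carry the gantry angle at 50 ms intervals, but column
layouts vary by control-software version, so parsing happens behind a
declared dialect (separator, angle scale, sample interval) rather than a
hard-coded vendor format. A matching writer ships with the package so the
comparison path round-trips in tests without a linac; round-trip error is
bounded by half the dialect's quantization step (0.05° at the default
scale 10).

Trajectory comparison samples the absolute circular deviation of the
reference (resampled onto the measurement's time grid) and reports mean,
SD and maximum. Decisions worth knowing:

* Interpolation always unwraps first and wraps after, so crossing the
  ±180° seam interpolates along the short arc.
* The SD is the 1-SD spread of the *absolute* deviations — the report-table
  convention here is not defined unambiguously in the source material, and
  this reading is recorded as the package's choice.
* Deviations are evaluated on the first trajectory's grid; the higher-rate
  source should come first.
* Clock synchronization defaults to **off**: reported deviation figures
  for this class of measurement conventionally include the residual
  synchronization error rather than fitting it away.
  An `auto` mode exists because synchronization is the dominant error
  source in practice: a grid search (±1 s, 1 ms steps) minimizes the mean
  circular deviation, with ties resolved to the smallest shift and boundary
  hits flagged. Motion onset (windowed angular speed above 0.5°/s over 5
  samples) doubles as the beam-on proxy and lets the static lead-in be
  excluded from statistics.

## Numerical and degenerate-input policy

* Angles live in `[0, 360)` raw and `[-180, 180)` calibrated;
  `to_gantry(theta0)` is exactly 0. Unwrapping assumes less than 180° of
  true motion between consecutive samples — amply satisfied at 30 Hz
  against a 6°/s speed limit.
* Median-filter borders replicate edges; dots never sit at the frame border
  in a valid setup, and the policy is chosen for testability.
* Component ties (equal areas) resolve to the first encountered in scan
  order; coincident centroids raise a classed error the analyzer converts
  to a gap sample.
* Empty masks, constant images, empty directories, non-monotone time axes
  and malformed log lines all produce classed, named errors rather than
  silent results.
* The rendered lead-in sits at 0° and the commanded trajectory follows
  immediately, so a plan that starts away from 0° begins with an
  instantaneous reposition in the commanded truth. Footage and truth share
  that frame exactly, so recovery statistics are unaffected; but when
  comparing against a reference resampled at a different rate, the jump
  spans one interpolation interval and produces a spurious deviation spike —
  window the measurement to the arc with `trim_trajectory()` first.
* The `"auto"` region-of-interest optimization fixes a processing window
  around the first detected dot pair (the rotation centre is static). The
  threshold is range-relative and the window always contains both dots and
  background, so cropping does not change detection results; an explicit
  property test pins the fused fast path to the composed public primitives.

## Problem sizes used in the shipped checks

The package's own validation runs, reproduced by `scripts/acceptance.R`,
use the default 720p geometry and noise model: 37 static angles at 10°
spacing with 90 frames (3 s) each plus a single 12 s calibration lead-in,
and all three QA plans rendered in both directions at 30 fps with 12 s
lead-ins (about 20,000 frames end to end). The unit-test suite exercises
the same code paths on a 320 × 240 scene with proportionally scaled
geometry, where the coarser angular resolution (~0.1° noiseless, versus
~0.05° at 720p) is expected and documented in the tests themselves.

## Known limitations

* No video-container decoding: footage is ingested as ordered PNG frame
  directories (or rendered in memory); extract frames with an external tool
  first.
* One dot pair, one camera; the multi-marker/arrow patterns and audio
  beam-on synchronization ideas floated in the literature are out of scope.
* The comparison module assumes both clocks run at the same rate; only a
  constant offset is estimated, not drift.
* Accuracy figures are established against the synthetic camera model, not
  against hardware references.
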
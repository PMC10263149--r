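---
title: "Tracking and analysing bee flight in wind: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and analysing bee flight in wind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeflight)
```

## What the package computes

`beeflight` reconstructs foraging-flight kinematics of bumblebees from
grayscale video of wind-tunnel and two-choice arena experiments, and
tests the behavioural questions those experiments pose: do bees prefer
to fly upwind, and how do their kinematics change with flow speed and
direction?

The measurement chain is the standard one for silhouette tracking:

1. **Background**: per-pixel temporal median of the frame stack. The
   median's 50% breakdown point makes the estimate exact wherever the
   moving bee covers a pixel in fewer than half of the frames, and
   immune to single corrupted frames.
2. **Detection**: absolute-difference thresholding against the
   background, connected-component labelling (via EBImage), and a
   moment-based ellipse fit per component. Orientation comes from the
   eigenvectors of the intensity-weighted second moments and is reported
   axially in [0, 180) degrees; semi-axes follow from the eigenvalues
   (a uniform ellipse with semi-axes $a, b$ has variances $a^2/4,
   b^2/4$).
3. **Association**: one constant-velocity Kalman filter per track
   (state: position and velocity in pixels), with detections assigned to
   track predictions per frame by minimising the total positional error
   under a gating radius. Unassigned detections open tracks; a track
   closes after `max_missed` consecutive misses.
4. **Pruning**: tracks shorter than 6 frames are dropped, and leading or
   trailing runs of at least 10 points that stay within 0.5 px of their
   anchor (a bee that landed, or a static false detection) are trimmed.
5. **Stereo** (choice arena): tracks from two synchronized views are
   paired by temporal overlap, triangulated linearly (DLT), scored by
   mean reprojection residual, and accepted greedily below a 5 px
   ceiling. The 3D paths support the walking filter (entire track below
   1.5 cm).
6. **Orientation refinement** (lateral high-speed view): see below.

From calibrated tracks the kinematics module computes travel-positive
ground speed along the tunnel axis (central differences by default; the
Kalman state velocity is available as an option), air speed as ground
speed plus flow when flying upwind and minus flow when flying downwind
(negative values meaning backwards flight relative to the air), path
sinuosity (path length over chord), body-pitch statistics, and wingbeat
frequency as the argmax of the FFT power spectrum of the silhouette
x-velocity within a 50–400 Hz search band after mean removal. The band
excludes the slow centre-of-mass component; the spectral resolution
$f_s/N$ is reported with every estimate and is the natural error bar of
the argmax estimator.

Inclusion filters mirror standard practice for this assay: flights with
sinuosity above 1.1 are excluded (reversals and loops corrupt the
optic-flow comparison), flights with mean ground speed below
0.02 m/s are treated as walking (the low mode of the bimodal speed
distribution), and wind-tunnel trajectories are restricted to the
central 30 cm of the 1.4 m working section, where bees are neither
taking off nor landing. Boundary values (S = 1.1, 0.02 m/s, 6-frame
tracks) are retained. Restriction is applied before the filters.

## Choice statistics

Daily two-choice outcomes are summarised as per-day proportions of
upwind (and right-channel) flights, and tested with a one-sample
Wilcoxon signed-rank test against 0.5, one-sided. Because the design has
only 12 days, p-values are exact: the null distribution of $V$ (the sum
of ranks of positive deviations) is enumerated over all $2^n$ equally
likely sign assignments through its generating function, which also
handles midranks when daily proportions tie. With 12 untied days all
above 0.5, $V = 78$ and the one-sided p-value is exactly $1/4096
\approx 0.00024$; enumeration of the same null puts $P(V \ge 58)$ at
$310/4096 \approx 0.076$. Per-day counts are tested with an exact
two-sided binomial test using the small-P rule (sum of all outcome
probabilities not exceeding the observed one). The two-sample Wilcoxon
rank-sum test enumerates all $\binom{m+n}{m}$ rank subsets when
$m + n \le 12$ without ties and otherwise uses the normal approximation
with tie and continuity corrections. Group effects of flow velocity use
one-way ANOVA from the textbook sum-of-squares decomposition with
Tukey–Kramer HSD (studentized range, harmonic-mean pair sizes) and a
tie-corrected Kruskal–Wallis test as the nonparametric check.

No repeated-measures correction is applied: individuals cannot be
re-identified across flights in this assay, so the flight-level tests
inherit pseudo-replication, which inflates type-I error. This is a
property of the design the package reproduces, documented rather than
silently "fixed".

## The synthetic-data module

Because raw videos of such experiments are rarely shareable, the
generator produces inputs with the statistical structure the analysis
assumes, with known truth:

- **Trajectories**: ground speed relaxes to a set-point (first-order,
  rate 5 s⁻¹) with Gaussian (discretised Ornstein–Uhlenbeck)
  perturbations; lateral and vertical position wander similarly. Body
  pitch is slaved to the commanded air speed by a linear gain with its
  own noise. The defaults encode the study conditions the package
  targets: set-point 0.8 m/s (observed preferred speeds span roughly
  0.7–0.9 m/s), base pitch 33.8° at zero flow and a gain of 4.3° per
  m/s of air-speed demand, the unique linear choice that reproduces the
  printed means of 33.8° with no flow and 42.4° in a 2 m/s tailwind;
  wingbeat 196.2 Hz. The qualitative control law (pitch down to speed
  up, pitch up to brake; air speed = ground speed ∓ flow) is what the
  experiments establish; the linear gain and the noise scales are the
  package's own modelling choices, selected once and documented here,
  not fitted to any test outcome. Downwind runs with a tailwind multiply
  the pitch and speed noise by 2 (configurable), reproducing the
  elevated kinematic variability of downwind flight.
- **Rendering**: flat-shaded dark body ellipse (13 × 5 mm) over a fixed
  speckled background, with 2×2 subsample edge anti-aliasing so that
  moment fits can recover subpixel geometry; in the lateral view two
  smaller wing ellipses oscillate in x at the wingbeat frequency
  (amplitude 5 mm), giving the silhouette velocity its fast component.
  Planar cameras are scaled-orthographic (500 px/m overhead over the
  full 1.4 × 0.45 m section at 100 Hz; 2000 px/m over a 10 × 10 cm
  lateral window at 5000 Hz; 50 Hz for the choice arena), stereo pairs
  are ideal pinholes with exact projection matrices standing in for a
  physical checkerboard calibration.
- **Choice sessions**: per-day upwind and right-channel counts are
  independent binomials; the defaults (12 days × 244 flights,
  p_upwind = 0.644, p_right = 0.525) are the observed study conditions.

What the generator deliberately does not emulate: photorealistic
appearance, aerodynamic forces, 3-D wing kinematics, occlusions between
bees, illumination drift, and individual identity. Passing tests on
synthetic data therefore demonstrate that the estimators are correct
and unbiased under the assumed statistical structure — not that the
pipeline is robust to every artefact of real footage.

## Orientation refinement

The raw ellipse orientation of a flying bee oscillates strongly within
each wingbeat because the wing silhouette fuses with the body. The
refinement step applies a per-pixel temporal quantile filter over a
window of at least one wingbeat period to a neighbourhood of the track,
motion-compensated by registering each in-window crop on the low-passed
track position (integer pixel offsets relative to the anchor frame, so
a stationary scene stays perfectly registered). The body darkens its
pixels for the whole window while a sweeping wing covers any one pixel
only briefly; an upper quantile (default 0.75) therefore restores the
background wherever wing coverage stays below that fraction. A plain
median (q = 0.5) fails exactly at the oscillation extremes, where a
sinusoidally moving wing dwells for up to half of a one-period window —
the quantile form is the same filter with a margin against that
breakdown. The filtered crop is re-thresholded against the identically
filtered static background and re-fitted; the 180° axial ambiguity is
resolved nose-forward along the direction of travel, making the signed
pitch invariant under mirroring the scene.

## Numerical and design choices

- **Assignment**: gated global-nearest-neighbour matching, solved
  exactly (dummy-padded enumeration) whenever tracks + detections ≤ 8,
  and greedily beyond. Scenes in this assay contain at most a few bees,
  so the exact branch covers practice; the exact solver is also what
  the oracle-equivalence tests exercise.
- **Kalman defaults**: process noise 0.5 px²/frame on a
  constant-velocity model, measurement noise 1 px²; new tracks start
  with diffuse velocity (variance 100 px²/frame²).
- **SD convention**: sample SD (n − 1) everywhere.
- **Sinuosity** of degenerate closed paths (start = end) is undefined;
  such flights are flagged, not errors.
- **Air speed** is computed by the add/subtract rule on travel-positive
  ground speed rather than a single signed formula, so summaries match
  the printed convention exactly; under constant flow the SD of air
  speed equals the SD of ground speed by construction.
- **Exact-test switchovers**: signed-rank enumeration up to n = 25;
  rank-sum enumeration up to m + n = 12 without ties. Beyond these,
  tie-corrected normal approximations with continuity correction.
- **Determinism**: every stochastic step draws from a seed carried in
  its parameter object, restoring the caller's RNG state afterwards;
  identical configuration and seed give identical output, including the
  pipeline report.

## Problem sizes used in the test-suite and demonstrations

Rendering every frame of every experiment is unnecessary for
validation; the suite simulates clips of 0.08–1.2 s (400–120 frames at
5000/100 Hz), batches of 6–40 flights for pipeline-recovery runs, and
10⁴ replicates for the type-I-error calibration of the exact
signed-rank test. These sizes were chosen so that each recovery check
has sampling error well below the tolerance it asserts (e.g. the
grand-mean air-speed checks use enough flights that the standard error
of the mean is below half the 0.05 m/s tolerance).

## Known limitations

- The walking filter for the choice arena needs 3D tracks; monocular
  overhead runs rely on the low-speed filter alone.
- The per-flight SD of air speed is mathematically identical to the SD
  of ground speed under constant flow; analyses that report them as
  separately informative quantities are reproducing a convention, not
  additional information.
- The greedy stereo pairing can mis-pair bees that cross in both views
  simultaneously with near-equal residuals; residual ceilings keep such
  pairs out of downstream analysis rather than resolving them.
- No individual re-identification across flights: statistics treat
  flights as independent (see the repeated-measures note above).
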
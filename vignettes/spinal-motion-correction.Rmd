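---
title: "Motion correction for awake spinal cord imaging: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion correction for awake spinal cord imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spinalmcm)
```

# The problem

One-photon fluorescence movies of the spinal cord in awake mice carry three
kinds of motion that standard calcium-imaging pipelines handle poorly:

1. **Large rigid shifts.** Locomotion drags the cord rostrocaudally by up to
   hundreds of pixels within a session. Gradient-descent intensity
   registration has a capture range set by its coarsest pyramid level and
   simply does not reach these displacements.
2. **Non-rigid deformation.** The cord stretches and compresses along its
   axis frame to frame, so even a perfect rigid fit leaves residual
   misalignment that varies across the field of view.
3. **Independently moving occluders.** Neovascularization, bubbles and
   debris overlie the tissue and move with their own dynamics; an
   intensity-based registration happily locks onto them instead of the
   cord.

The package's three correction tiers address these in order, and are
designed to compose: feature-based rigid correction first (LD-MCM), then
constrained non-rigid correction (NR-MCM), then cross-session alignment
(CS-MCM).

# LD-MCM: control-point rigid correction

Stable vasculature landmarks (the dorsal vein and ascending venules) are
tracked across frames — by any tracker that emits per-frame positions with
confidences; the package reads the common pose-estimation CSV dialect
(`readFeatureTable`) and ships a normalized-cross-correlation template
tracker (`trackFeaturesNCC`) for self-contained use. Records with
likelihood at or below 0.99 are dropped per frame.

Each frame's transform is **rigid** (rotation plus translation, no scaling
or skew): rigidity preserves the image mass and leaves residual non-rigid
motion for the next tier. The fit is a random-sample consensus: 1,000
random point pairs each propose a rigid transform; proposals are scored by
how many correspondences land within 20 px; the best proposal is refit on
its inliers by 2-D Procrustes without scaling, with ties broken by the
smaller inlier RMS error. Two parameters matter:

- `trials` (default 1000): with inlier fraction `w`, the chance that no
  trial draws two inliers is `(1 - w^2)^trials`; at `w = 0.5` this is
  below 1e-100, so recovery failures come from structured outliers, not
  sampling.
- `inlierPx` (default 20): the gate must exceed tracking jitter by a wide
  margin while rejecting mistracks; 20 px does both for vasculature
  tracking whose jitter is well below a pixel to a few pixels.

Three robustness layers surround the consensus fit, each motivated by a
concrete failure mode observed on simulated data:

- **Rotation bound** (`maxRotationDeg = 30`): a pair of outlier tracks can
  propose a transform with a large rotation that accidentally gathers a
  third outlier. The field of view physically cannot spin or flip, so
  candidates beyond 30 degrees are rejected outright.
- **Consensus reference refinement** (`refinementRounds = 2`): registering
  every frame against one reference frame's records makes that frame's
  outliers systematic errors, and distant frames share few visible
  landmarks with it. After a first pass, each feature's reference position
  is re-estimated as the per-component median of its transformed positions
  over all frames, and the fits are repeated. The consensus reference also
  gives features that are out of view on the reference frame a usable
  anchor, which matters once shifts approach the field-of-view size.
- **Temporal-consistency guard**: cord motion is continuous, so a fitted
  shift that leaps more than `2 * inlierPx` from the 5-frame running median
  of its neighbours is discarded; such frames (and frames with fewer than
  `minInliers` usable features) inherit the nearest corrected frame's
  transform and are flagged rather than silently passed.

A final **residual pass** estimates a per-frame translation (phase
correlation) on an automatically chosen subregion — high mean-frame
contrast, low temporal variance, few missing pixels, i.e. away from
occluders — to absorb frame-to-frame feature-localization jitter. The
residual is capped at 5 px and applied only when it actually improves the
frame's correlation to the reference, so a biased estimate can never make
alignment worse.

# NR-MCM: axis-constrained demons fields

Displacement fields are estimated with multi-resolution demons
registration: 3 pyramid levels (factor 2), 2000/400/100 iterations
coarsest-first, and Gaussian smoothing of the accumulated field with
σ = 1.5 px applied at every iteration. The update force is the classic
intensity difference scaled by gradients; the package uses the symmetric
form (average of fixed-image and warped-moving gradients), which measurably
improves recovery when the deformed image is the moving one. Iteration
within a level stops early once the mean per-pixel update falls below
`stopTol` (default 1e-3 px) — the configured budgets are upper bounds, and
the identity case exits after a single sweep.

Fields are estimated on the registration-normalized movie (mean
subtraction, pillbox-background subtraction with radius one tenth of the
smaller frame dimension, disk-3 smoothing, complement so vessels are
bright) and applied, with linear interpolation, to the analysis movie
(typically the bandpass-divided movie; the two-track flow is explicit via
`runNRMCM(..., applyTo = )`).

The **mediolateral constraint** (`constrainToRC = TRUE`) holds the
mediolateral component at zero *throughout the iterations*, not merely in
the emitted field. This is deliberate: the dorsal vein runs along the
rostrocaudal axis, so the image often gives no lateral evidence (an
aperture problem), and an unconstrained solver can drift sideways by
several pixels and then mis-attribute rostrocaudal structure. Solving in
the constrained space avoids that failure and makes `max |u_ml| == 0`
exact by construction. The documented cost is that genuinely mediolateral
deformation is left uncorrected (a test pins this behavior down).

A rigid (translation) residual pass follows, gated the same way as in
LD-MCM.

# CS-MCM: cross-session alignment and cell matching

Per-session mean frames are padded to a common shape with *missing-value*
pixels (not zeros), so pads never enter correlations or fits. Alignment is
initialized from user-supplied integer offsets or feature tracks — the
automated stand-in for an operator's coarse manual shift — then refined by
an affine fit without rotation or skew followed by an affine fit with
rotation and no skew (`estimateAffine`).

The affine estimator is a coarse-to-fine Gauss-Newton on the sum of
squared differences, with several numerical choices that proved necessary:

- Missing pixels stay missing through the pyramid (NA-aware block means,
  normalized-convolution smoothing that erodes rather than extrapolates at
  borders), so out-of-overlap regions cannot bias the optimum.
- The nominal 30 px smoothing is converted to a per-level Gaussian σ capped
  at 2.5 px: pyramid levels are already band-limited, and heavier blur was
  measured to bias converged translations by several pixels across
  missing-data borders.
- The scale/rotation center is anchored on the centroid of the current
  valid overlap, which after a 100 px shift sits far from the image center;
  a distant center couples scale to translation and destabilizes the fit.
- Per-axis scales are bounded to [0.8, 1.25] (`scaleBounds`): sessions
  share their optics, and unbounded scales admit a texture-aliasing
  attractor in which a large stretch of blurred texture accidentally
  matches. Parameter steps are damped per iteration, and the best
  parameters by overlap-penalized mean residual are kept, guarding against
  the overlap-shrink degeneracy (a tiny accidentally matching sliver).

Aligned sessions can be concatenated and every frame re-registered to one
reference frame (`refineConcatenated`, with a frame-count guard above which
batch processing is required), and per-session quality is reported as
Pearson and Spearman correlations to the reference, optionally on
Frangi-enhanced frames (min-max normalized first, so brightness and gain
changes across sessions drop out).

**Cell matching** works on footprints mapped into reference coordinates.
Candidate cross-session pairs within the centroid gate (5 px default, 15 px
permissive) are ordered globally by distance and accepted greedily when
both cells are unmatched, at most one cell per session joins a global
identity, and the footprint shape correlation exceeds 0.6. Shape
correlation compares centroid-centered crops, so a residual offset within
the distance gate does not masquerade as a shape difference. The global
distance ordering makes two-session matching symmetric; additional rounds
re-estimate per-session residual shifts from current matches and rematch.

# Vessel diameter

The per-frame chain: min-max normalize, histogram-match to a reference
frame by mid-rank quantile mapping (exact on tied histograms), scale by
150; multiscale Frangi vesselness (σ = 1–20 step 2, β₁ = 0.5, β₂ = 15,
dark-ridge polarity) from γ-normalized Hessian eigenvalues, maximum over
scales; threshold; per-frame local thickness; mean thickness over the ROI.

Two gates define the vessel mask. The vesselness threshold (0.03)
suppresses non-vascular structure but — because the scale-space union
spreads a ridge response well beyond the vessel at large σ — cannot by
itself delineate the boundary. The boundary comes from the gray-value
threshold of the local-thickness step (40, alternatively 80, on the
complemented 0–150 intensity scale), which is how the two printed
thresholds become commensurable: one is a vesselness level, the other an
intensity level. On clean bar phantoms this chain recovers widths of 5, 9
and 15 px exactly.

Local thickness uses the unit-square pixel model: the inscribed radius at a
foreground pixel is its exact Euclidean distance to the nearest background
pixel minus 0.5, and every pixel covered by a disk takes the largest such
diameter. The implementation (exact distance transform plus disk painting)
agrees exactly with a brute-force inscribed-disk search on all test masks.
Thickness is computed on every frame independently — treating the movie as
a 3-D volume would leak information across time.

# Scalar quantifications

The behavior formulas are direct transcriptions: quadrature decoding with
`CW = (A > B) > diff(A)` and `CCW = -((B > A) > diff(B))`, speed
`|CW + CCW| * Cp * rate` with `Cp = 2 pi r / 600`; body-part speed from
frame-to-frame distances with a 0.1 likelihood gate, gap-aware timing, and
a 5 s moving mean where requested; SUDO thresholds
`10^(0.24 (F ± 0.5) - 1.54)` (+0.5 when the animal did not respond);
Chaplan `10^(log10 F + k D)` with `k` supplied by the user (the published
lookup tables are user data; the package deliberately ships no values it
cannot source); the microglial asymmetry ratio
`(F_ipsi - F_contra) / (F_ipsi + F_contra)` with baseline-session
subtraction; response maps as post-stimulus window means, median filtered,
with "outermost" contours defined as those not nested inside another
contour at the same level.

One printed formula required interpretation: the 8-bit conversion rescale
is implemented as `Mf = round(255 (0.01 + 0.99 M1))`, which realizes the
stated intent (shift all values up so none are fully dark) with a minimum
output of 3. The quadrature decode formulas count each emitted one-sample
pulse exactly once; a sustained high state would be counted repeatedly,
which the synthetic generator therefore never emits.

# The synthetic generator: what it does and does not emulate

`simConfig`/`makeMovie` render: bright tissue (smooth plus capillary-scale
texture), a curving dark dorsal vein with branching venules plus a
scattering of smaller vessels (`nExtraVenules = 8` — the vessel density a
real field of view carries, and what makes deformation observable away
from the main vein), two lateral strips of Gaussian-blob neurons with
Poisson-event, exponential-decay transients (τ = 1.5 s, a slow-indicator
scale), a smooth bout-like rostrocaudal shift schedule rescaled to hit the
configured maximum exactly, per-frame jitter, a field-of-view-scale
sinusoidal rostrocaudal deformation (wavelength 256 px by default — the
cord bends along its length rather than rippling at vessel scale), an
independently drifting bright occluding layer, exponential photobleaching,
and Poisson plus Gaussian read noise. Ground truth (shifts, field
parameters, per-frame feature positions, traces, widths, bleach) is exact;
for non-rigid frames feature positions solve the warp's fixed-point
equation to numerical precision. At 2.5 µm/px, shifts of 260 px correspond
to the >650 µm excursions seen in vivo.

Passing tests on this generator demonstrate that the algorithms recover
known motion under realistic structure, occlusion and noise. They do not
demonstrate robustness to everything real data adds: slow focus drift,
blood-flow shadows inside large vessels, indicator photoswitching,
non-stationary noise, or deformation that is not predominantly
rostrocaudal. The benchmark problem sizes used by the test suite and the
acceptance script — a 256 × 256 × 500 movie with 120 px shifts for LD-MCM,
128 × 128 × 300 with 8 px deformation for NR-MCM, three 192 × 192 sessions
with up to 100 px offsets and 2 degrees of rotation for CS-MCM — were
chosen as the smallest sizes that still exercise the stated motion
regimes. The non-rigid benchmark simulates deformation and jitter without
cell transients: transient-active cells are real scene changes, not
motion, and (as a dedicated test documents for the mediolateral case)
demons will chase any structure its constraint leaves it free to chase —
on real movies this is mitigated because fields are estimated on the
pillbox-normalized representation that suppresses blob-like structure.

# Known limitations

- Rigid LD-MCM requires at least two well-tracked landmarks per frame;
  frames below that inherit a neighbour's transform (flagged, never
  silent).
- The mediolateral constraint trades lateral correction away by design.
- Cross-session affine alignment needs the cord (not just featureless
  tissue) inside the inter-session overlap; mediolateral offsets that push
  the vasculature out of the overlap leave the fit under-constrained.
- TIFF storage is 32-bit quantized; bit-exact round trips are the HDF5
  path's job. 8-bit AVI is not read or written.
- Cell matching is greedy (globally distance-ordered); an optimal
  assignment could differ in dense maps where gates overlap.
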
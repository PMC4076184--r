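---
title: "Co-activation pattern analysis: models, choices, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-activation pattern analysis: models, choices, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

Seed-based co-activation pattern (CAP) analysis rests on the observation
that a static seed-correlation map is an *average* over transient,
spatially distinct brain configurations. Instead of correlating every
voxel with the seed over the whole session, the session is reduced to a
spatio-temporal point process: the frames at which the standardized seed
signal exceeds a threshold (1 SD by default, which for an approximately
Gaussian trace keeps `1 - pnorm(1)`, about 15.9%, of time points). The
whole-brain maps at those frames are clustered by spatial similarity
with k-means (K = 8 by default), and each cluster's average map is one
CAP. Occupancy — how many frames fall in each cluster — and the CAP maps
themselves can then be compared across experimental conditions, e.g.
levels of propofol sedation (wakefulness, sedation, unconsciousness,
recovery).

Two properties make the decomposition well-behaved:

* **Conservation.** The occupancy-weighted mean of the K CAPs equals the
  grand mean of all selected frames exactly (up to float tolerance), so
  the CAP set is a genuine decomposition of the seed's average
  supra-threshold map. The test suite asserts this identity at `1e-8`
  for every condition.
* **Fixed centroids.** To compare CAP *j* in one condition with CAP *j*
  in another, cluster indices must mean the same thing in both. The
  package therefore separates `fit_centroids()` (run once, on a
  reference data set) from `assign_to_centroids()` (nearest-centroid
  labelling that never updates the centers). Tests check the centroid
  matrix is bit-identical before and after assignment.

## Processing chain

`preprocess_session()` applies, in order: polynomial detrending
(order 2), zero-phase Butterworth bandpass (0.005–0.1 Hz, order 2 per
pass), nuisance regression, Gaussian spatial smoothing, and voxelwise
standardization to mean 0 / SD 1.

Choices that were genuinely open, and how they were settled:

* **Stage order.** Published descriptions of this preprocessing list the
  steps without an order. Detrending precedes filtering so slow drift
  does not interact with the 0.005 Hz band edge; regression precedes
  smoothing so nuisance fits happen at native resolution; and
  standardization is last because all later stages interpret values in
  SD units. The order is configurable per call.
* **Filter–regressor consistency.** The nuisance regressors are passed
  through the *same* detrend and bandpass operations as the data before
  regression. Regressing filtered data on unfiltered regressors leaves
  the regressors' in-band content partially unremoved (the regression
  coefficient is shrunk by the out-of-band variance). In synthetic runs
  this residual global signal produced spurious seed-threshold
  crossings far from any planted event, so the consistency rule is not
  cosmetic — it is required for the point process to mean what it
  claims.
* **Filter family.** A zero-phase (forward–backward) Butterworth was
  chosen because phase distortion would shift BOLD peaks in time and
  the point process is defined by peak timing. Each column is demeaned
  before filtering; DC is below the low cutoff in any case, and a
  demeaned input avoids the slow step transient of the 0.005 Hz edge.
* **SD convention.** The sample SD (denominator *n* − 1) everywhere,
  fixed so that results are bit-reproducible and testable. Voxels whose
  SD is below `1e-8` times the largest voxel SD are treated as
  zero-variance, set to 0 and counted; the relative threshold also
  catches the float residue that exact-arithmetic cases (e.g. a pure
  quadratic drift after order-2 detrending) leave behind.
* **Smoothing boundaries.** Separable Gaussian convolution with
  *reflective* boundary handling, so small synthetic grids do not dim at
  the edges; the kernel is renormalized to sum 1 and the impulse
  response equals the closed-form 3D Gaussian constant at the center,
  which the tests check at 2%.

## Motion quality control

FD is the sum of absolute frame-to-frame changes of the three
translations (mm) plus the three rotations converted to arc length on a
50 mm sphere — the conventional head radius. DVARS is the RMS over
in-mask voxels of the frame-to-frame intensity difference, in percent
of the session's grand-mean intensity, computed on data *before*
standardization ("% BOLD" has no meaning after per-voxel z-scoring).
The default censoring rule flags a frame only when FD > 0.5 mm **and**
DVARS > 0.5% — the joint rule used in the propofol CAP literature — but
`rule = "or"` is offered because the scrubbing literature's original
convention censors when either index exceeds its threshold; the package
exposes the discrepancy rather than hiding it. Whether censoring should
precede frame selection is ambiguous in published practice; the
pipeline applies it before selection by default
(`qc$apply_censoring`), and `glance()` on a point process reports the
selected fraction both relative to all frames and to
censoring-surviving frames.

## Seed and selection

The seed is a cube (6 mm edge by default) resolved to every voxel whose
center falls inside it; with 3 mm voxels this is at most 2 × 2 × 2
voxels. For MNI-space use the canonical posterior-cingulate seed is
(0, −53, 26); note the negative y — PCC is posterior, and printed
coordinates sometimes drop the sign, so the default is flagged in the
documentation and fully configurable. The seed trace is the mean of the
seed voxels re-standardized to SD 1, and the threshold uses a *strict*
inequality (`> threshold_sd`): a measure-zero choice, but it must be
pinned for exactness tests. All consecutive supra-threshold frames are
kept by default — selection targets "time points", not peaks of peaks —
with `peaks_only = TRUE` available to restrict to local maxima.

## Clustering

Frames are centered and unit-normalized before Euclidean k-means, which
orders pairs identically to 1 − Pearson correlation — the CAP
literature's similarity notion — while keeping the simple Lloyd update
valid. Initialization is kmeans++ with 10 restarts, the best run by
within-cluster sum of squares is kept, and the RNG seed is recorded in
the centroid set's provenance so a fixed-centroid baseline is exactly
reproducible. Distance ties in assignment break toward the lowest
centroid index (deterministic and testable). CAP averaging uses the
standardized but *per-frame-unnormalized* maps so CAP amplitude retains
its meaning in BOLD-SD units; display normalization is a separate
concern (`plot_voxel_maps()` shows raw values). K is fixed at 8 by
default and no model selection over K is attempted.

## Group statistics

Per-condition significance is a voxelwise one-sample t across subjects'
CAP maps against 0, one-sided for co-activation. The cross-condition
test is a *within-subject contrast*: for each subject the combination
`sum_c w_c map_c` with weights summing to zero — default
(1.5, −0.5, −1.5, 0.5) over wakefulness, sedation, unconsciousness,
recovery, with recovery down-weighted relative to wakefulness because
residual anesthetic keeps recovery below true baseline — followed by a
one-sided one-sample t on the subject contrasts and Benjamini–Hochberg
FDR at q = 0.05. The SPM-style repeated-measures ANOVA with
non-sphericity correction tests the same one-sided hypothesis under
this contrast, but the within-subject formulation needs no sphericity
assumption at all and is exactly reproducible from first principles;
this substitution is deliberate and documented. The contrast is
computed on differences from the first condition, which makes a
condition-constant data set give an exactly zero contrast rather than a
float-level one. Zero-variance voxels return a documented sentinel
(t = ±Inf with p = 0 or 1; t = 0, p = 0.5 for all-zero voxels), never
NaN. Whether second-level input should be individual frames or
subject-mean maps is ambiguous in published descriptions; this package
uses subject-mean maps (subjects as random effects), excluding subjects
with empty condition cells pairwise with a message.

Seed-correlation maps and sliding-window correlation maps are provided
as the static and dynamic baselines that CAP analysis refines; a window
spanning the whole session reproduces the static map exactly.

## The synthetic cohort generator

No public data accompany the propofol study this design emulates, so
`generate_cohort()` plants known structure on a synthetic grid:

* K distinct spatial patterns, each two Gaussian blobs (σ = 1.6 voxels,
  truncated at 3σ) in lattice cells assigned to one pattern only, so
  pairwise pattern correlation stays far below 0.5 by construction;
* per-frame Bernoulli events (rate 0.15 by default, matching a ~15%
  supra-threshold fraction), each expressing one pattern drawn with
  probability proportional to the condition × pattern gain matrix and
  convolved with a canonical double-gamma HRF (peak ≈ 5 s, undershoot
  ≈ 15 s, sampled at TR = 2.46 s);
* a positive seed-cube amplitude at every event regardless of pattern,
  so the seed peaks whenever any pattern is expressed;
* a brain-wide slow "physiological" fluctuation (smoothed white noise,
  SD 2 a.u. against a 1000 a.u. baseline). Its size is deliberately
  large relative to a single event (4 a.u.): the global-mean regressor
  is then physiology-dominated, as in real data. When the global signal
  was instead dominated by the planted patterns, global-signal
  regression induced the classic artifactual anticorrelation and a
  spurious ninth frame class — an instructive failure, not a usable
  regime;
* per-voxel linear + quadratic drift, i.i.d. Gaussian noise, and
  motion spikes: a persistent 0.8 mm translation step in the motion
  trace plus a single-frame 1% global intensity blip, so FD and DVARS
  flag the same frames under the joint rule. Spikes are placed with a
  minimum gap of two frames (adjacent corrupted frames would mask each
  other's DVARS excursion), at per-condition rates defaulting to
  5%, 3%, 8% and 1% — the ordering reported for the four sedation
  conditions. Default sizes follow the emulated protocol: 18 subjects ×
  4 conditions × 197 frames at TR 2.46 s on a 20 × 24 × 20 grid of 3 mm
  voxels.

What the generator does **not** emulate: structured cardiac or
respiratory noise, susceptibility artifacts, slice timing, spatial
normalization, anatomical tissue contrast (WM/CSF nuisance ROIs are
caller-supplied stand-in masks), or spatially varying HRFs. Passing
tests on this generator show the machinery is correct and the planted
parameters are recoverable; they do not show that real propofol data
contain eight patterns or that the published regional findings
replicate.

## Validation design and problem sizes

The test suite and the acceptance script run at sizes chosen to make
each property measurable at desk scale:

* the null frame-selection check uses 18 sessions × 197 frames, the
  emulated protocol's own size;
* the pattern-recovery experiment uses 4 subjects × 4 conditions × 197
  frames with `k_true = 8`, amplitude 4, noise SD 0.3, and event rate
  0.08 — sparser than the 0.15 default. This is a deliberate
  identifiability choice, not a tuning: at rate 0.15 with a ~5 s HRF,
  most supra-threshold frames superimpose two or more patterns, so
  single frames cease to be labelable by *any* method, independent of
  noise. At rate 0.08 frames are single-pattern-dominated and all 8
  planted patterns are recovered above r = 0.7 (the per-voxel
  standardization saturates blob cores, which caps the attainable
  correlation near 0.8 — the remaining gap is a property of z-scored
  amplitudes, not of the clustering);
* type-I control of the linear contrast uses 200 replicates of a
  10-subject, 100-voxel null; power uses 20 replicates with a planted
  monotone gain profile (1, 0.6, 0.2, 0.9);
* BH-FDR is compared against a brute-force step-up enumeration on every
  p-vector of length ≤ 6 over a fixed 6-value grid.

## Known limitations

* Real-data preprocessing (realignment, coregistration, normalization
  to MNI) is out of scope; sessions are assumed aligned on a common
  grid, as synthetic data are by construction.
* HRF deconvolution before frame selection is an extension point, not
  implemented.
* The k-means model fixes K; an inappropriate K merges or splits
  patterns silently (diagnosable via occupancy and similarity tables).
* Fitting reference centroids on the analysis cohort itself (the
  pipeline default when no centroid file is supplied) is a pragmatic
  stand-in for an independent reference data set; for real studies a
  held-out cohort should supply `cluster$centroids_file`.
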
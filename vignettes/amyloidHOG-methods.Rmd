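---
title: "Amyloid-status classification with 3D histograms of oriented gradients: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amyloid-status classification with 3D HOG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Amyloid PET scans are read as amyloid *positive* or *negative*. The standard
quantitative adjunct, the composite standardized uptake value ratio (SUVR),
needs tracer-specific target/reference regions and a tracer-specific
positivity threshold, both of which shift between quantification pipelines.
This package implements a region- and threshold-free alternative: a global
image descriptor built from histograms of oriented 3D gradients (3D HOG),
classified with an RBF-kernel support vector machine, together with the two
comparator methods it is usually evaluated against (composite SUVR with
cross-scale threshold conversion, and an SVM on z-normalized voxel
intensities) and a synthetic phantom generator so every pipeline can be
exercised end to end without clinical data.

The scientific intuition: a negative scan shows strong local contrast
between white matter (high non-specific uptake) and grey matter (low
uptake); cortical amyloid raises grey-matter uptake and *erases that local
contrast*. Local gradient orientation histograms capture exactly this
contrast structure, while being insensitive to the absolute intensity scale
and to smooth spatially varying intensity modulations.

## The descriptor

Input volumes are assumed skull-stripped, affinely registered to a common
(MNI-like) space and resampled to isotropic voxels (2 mm is the working
default; `readVolume()` refuses anisotropic input rather than resampling,
since registration/resampling belongs to the upstream pipeline).

1. **Gradient field.** Per-voxel central differences (one-sided at the
   volume faces), in intensity units per voxel. Spacing is deliberately not
   folded in: the descriptor uses orientations and relative magnitudes
   only, and isotropy is enforced upstream.
2. **Integral gradient volume.** Each gradient component is cumulatively
   summed over all three axes, so the sum over any axis-aligned cuboid is
   an 8-corner inclusion–exclusion lookup, O(1) per cuboid. Accumulation is
   in double precision: cumulative sums over ~10^6 voxels are not safe in
   single precision. The corner signs follow the standard 3D pattern and
   are verified against a brute-force triple-loop oracle in the tests. The
   mean gradient of a cuboid is this sum divided by its voxel count w·h·d
   (the division is occasionally omitted when the construction is written
   down; the arithmetic mean is the quantity that makes the sub-block
   votes commensurate across block sizes).
3. **Cells and sub-blocks.** The volume is partitioned into a uniform grid
   of k×k×k-voxel cells, each split into S×S×S sub-blocks of edge k/S. The
   mean gradient of every sub-block is computed from the shared integral
   volume, never re-differenced per cell. Partial cells at the volume edge
   are discarded, with the cell lattice anchored at the centered offset
   `floor((dim mod k)/2)` so the discarded margins are symmetric; this
   keeps every histogram supported by exactly k^3 voxels and therefore
   comparable. For the default 80×96×80 grid and k = 16 this yields
   5×6×5 = 150 cells.
4. **Orientation quantization.** A mean gradient g votes into the bins of a
   regular polyhedron: q̂ = P·g/‖g‖, where the rows of P are the unit
   face-center directions of a dodecahedron (12 bins) or icosahedron
   (20 bins), built from the standard golden-ratio coordinates (the two
   solids are duals: each one's face centers are the other's vertices). In
   *half-orientation* mode one face of each antipodal pair is kept and
   |q̂| is used, making the vote — and hence the descriptor — invariant to
   gradient sign and to global intensity inversion. The projection
   threshold t is the maximum pairwise dot product among distinct,
   non-antipodal faces of the full set (the adjacent-face cosine): it is
   the unique choice for which a face-aligned gradient votes in exactly
   one bin. t is subtracted from q̂, negatives are clamped to zero, and
   the result is rescaled to ‖g‖, so the vote's L2 norm equals the
   gradient magnitude (checked to 1e-9 over 10^5 random gradients).
5. **Cell histograms and concatenation.** The S^3 sub-block votes of a cell
   are summed into that cell's histogram; histograms are concatenated
   x-fastest with bins contiguous per cell. With the default parameters
   (below) the feature vector has 150 × 10 = 1500 elements.

### Numerical choices

* Zero gradients vote zero (masked PET volumes contain large constant
  regions); they are not an error.
* After threshold subtraction, entries ≤ 1e-9 are clamped to zero so a
  gradient aligned exactly with a face center does not leak floating-point
  residue into the adjacent bins.
* If the thresholded projection vanishes for a nonzero gradient (possible
  only if t exceeded the covering cosine of the face set — it does not for
  either solid, as the tests assert over 10^5 random directions), the full
  magnitude falls back to the best-aligned bin, lowest index on ties, and
  the event is counted in the `"fallbacks"` attribute.
* In half mode the full-set threshold is inherited by default;
  `makePolyhedron(..., thresholdMode = "folded")` recomputes it on the
  folded set (for both solids the two coincide).
* One sentence-level ambiguity in the descriptor's usual description —
  whether sub-block votes are summed within a cell or concatenated across
  sub-blocks — is resolved in favour of summation (that is what the
  defining equation says); `HOGParams(concatSubblocks = TRUE)` provides the
  alternative reading.
* Per-cell L2 normalization (ε = 1e-12) exists behind
  `HOGParams(normalizeCells = TRUE)` but is **off** by default: the
  magnitude weighting of the votes is part of the descriptor, and the 3D
  formulation defines no cell normalization.

### Parameters

| parameter | default | meaning |
|---|---|---|
| k | 16 voxels | cell edge; dominates performance, very small/large k hurts |
| S | 1 | sub-blocks per axis (1 = no sub-blocks), S ∈ {1, 2, 4} |
| polyhedron | icosahedron | 20 faces → 10 half-orientation bins |
| orientation | half | sign-invariant bins |

The defaults are the optimum configuration from the descriptor's grid
search on amyloid PET (cell size 16 voxels = 32 mm at 2 mm spacing, no
sub-blocks, icosahedron, half-orientation). `enumerateParamGrid()` exposes
the full 96-combination grid (k ∈ {4, 8, …, 32}, S ∈ {1, 2, 4}, two
solids, full/half).

## Classification

`trainSVM()` fits a soft-margin RBF-kernel SVM (libsvm via e1071). HOG
features enter unscaled — their magnitudes are already commensurate —
while the intensity baseline z-normalizes per image upstream.
`gridSearchCV()` selects (C, γ) from C = 10^{−2..3}, γ = 10^{−5..2} by
ten-fold stratified cross-validation: subjects are shuffled with the seed
within each class and dealt round-robin, so every fold has the same class
proportions and the assignment is reproducible without depending on any
library's internal shuffling. The pair maximizing mean fold accuracy wins;
ties break by higher pooled sensitivity, then specificity, then a
degeneracy guard, then smaller C and smaller γ.

**The degeneracy guard.** On a perfectly balanced, well-separated cohort —
exactly what the phantom generator produces — *every* grid pair can reach
cross-validated accuracy 1.0: with γ·‖x−x′‖² ≈ 0 the kernel is nearly
constant and the machine degenerates to an effectively linear classifier
that still separates balanced folds; with γ·‖x−x′‖² huge it memorizes the
training set. Both extremes reduce a genuinely unseen point to a majority
vote the moment the training set is imbalanced by a single subject — which
is precisely what every leave-one-out fold does — so a tie-break toward
the smallest C and γ would systematically select a model that fails
leave-one-out evaluation while looking perfect in cross-validation.
Candidates are therefore examined in tie-break order and the first one
passing a two-fit internal probe is selected: retrain with the first
subject of each class held out and require that subject to be classified
correctly. The probe uses training data only, is deterministic, and adds
two fits per examined candidate.

`leaveOneOut()` fixes the hyperparameters once (they are selected on an
independent training set, not re-tuned per fold), trains n models on n−1
subjects and predicts the held-out one, and reports accuracy, sensitivity
(amyloid-positive is the disease class throughout), specificity, signed
decision values, cohort-normalized distances (divided by the maximum
absolute value, so the largest-magnitude subject sits at ±1 — this also
removes the margin-width factor that separates decision values from
geometric distances), and ROC/AUC. `rocAuc()` sweeps the threshold over
the observed scores and integrates trapezoidally, which with tied scores
grouped equals the Mann–Whitney rank statistic (ties counted half); the
tests verify this against an O(n²) pairwise oracle and against pROC.

## SUVR and threshold conversion

`compositeSUVR()` computes each target region's mean uptake over the mean
reference uptake and averages the regional SUVRs unweighted (a
volume-weighted variant exists behind a flag). The positivity decision is
*strictly* greater-than: a composite exactly at the threshold is negative
(equality is a measure-zero event; the strict reading matches the
convention "SUVR > threshold"). Built-in thresholds: florbetapir 1.12,
florbetaben 1.36, PiB-on-sPAP 1.15. The PiB value descends from the
cerebellar-grey threshold 1.465 through two published affine regressions
(0.67·t + 0.15, then 0.9782·t + 0.04264); `jagustToSpap()` composes them
*exactly* rather than using the rounded printed coefficients, and
`jagustToSpapCoefficients()` reports the composed slope/intercept rounded
to 4 decimals (0.6554, 0.1894) for verification. Region masks are supplied
by the user as an integer-label NIfTI plus a JSON name/role map; the
package ships no atlas (template-region definitions are
pipeline-proprietary) but the phantom generator emits matched region sets.

## The intensity baseline

The comparator method flattens all voxels inside a brain mask (dilated by
2 mm so registered brains sit wholly inside) into one feature vector in
deterministic x-fastest order and standardizes it per image to zero mean,
unit variance. Population variance is used (the distinction is negligible
at ~10^5 voxels) and the statistics are computed within the mask, since
the vector is built from masked voxels only. Standardization makes the
features invariant to positive affine intensity rescaling — but not to
spatially varying modulation, which is the point of the comparison with
the gradient-based descriptor.

## The phantom generator

`generatePhantom()` builds an idealized brain: an ellipsoidal white-matter
core (intensity 2.0) inside a grey-matter shell (1.2) — the negative-scan
contrast — plus an inferior, disjoint cerebellum-like reference blob at
grey-matter intensity. Six 60° azimuthal sectors of the shell act as the
target regions, mirroring the six-region composite. An amyloid-positive
phantom multiplies the sector grey matter by the uptake factor (default
1.5), reproducing the grey/white contrast loss; because the reference
intensity equals the grey-matter intensity, the noiseless, unblurred
composite SUVR equals the uptake factor exactly, giving the quantification
tests a closed-form truth. The measurement chain then applies, in order:
an isotropic Gaussian PSF (FWHM 8 mm, typical of clinical amyloid PET), a
multiplicative low-frequency bias field (one oblique cosine with random
phase and direction, amplitude ±10% by default) emulating scanner- and
site-dependent intensity variation, and additive Gaussian noise
(sd 0.1, about 8% of grey-matter intensity). All geometry scales with the
grid so the same generator runs at reduced resolutions. Randomness is
drawn from a private seeded Mersenne-Twister stream that never disturbs
the caller's RNG, and the draws do not depend on the uptake factor, so
specs differing only in uptake share bias and noise exactly — enabling
paired contrast experiments. Cohorts add per-subject jitter (±10% on the
three tissue intensities, ±1 voxel on the cerebrum semi-axes).

What the phantom does **not** emulate: anatomy (gyri, ventricles, skull
remnants), tracer kinetics, attenuation/scatter artefacts, registration
error beyond the axis jitter, and inter-scanner PSF variation. Passing the
end-to-end recovery test therefore shows that the implementation chain —
generator → descriptor → selection → evaluation — is self-consistent under
a realistic contrast/noise model, not that the method reaches any
particular accuracy on clinical data.

## Problem sizes used by the test suite

The suite runs the full recovery experiment at the native 80×96×80
resolution with 30 positive and 30 negative phantoms (seed 0), and the
descriptor-vs-brute-force equivalences on volumes up to 48³; gradient and
integral oracles use explicit triple loops on grids up to 16³, and the
conservation suite draws 10^5 random gradients. The bias-sensitivity check
uses 8+8 subjects at 40×48×40 with a thinned hyperparameter grid (3 C ×
3 γ values through the same selection procedure), since the experiment
needs two cohorts and two full tuning runs.

### Why the phantom cannot reproduce the bias-robustness *comparison*

A natural expectation is that the gradient descriptor should degrade more
slowly than the voxel-intensity baseline as the multiplicative bias grows,
since local gradients ignore smooth intensity modulation. In this phantom
the direction actually *reverses* at high amplitude: the idealized brain
is piecewise constant, so most cells contain no structural gradient at
all, and the bias-induced gradient (proportional to amplitude × intensity
× the field's spatial frequency) becomes the dominant content of those
cells — with per-subject random bias phase and direction, that is pure
class-uncorrelated variance injected straight into a descriptor whose
informative entries are small. Per-image z-normalized intensities, by
contrast, retain the large class contrast of the target sectors. The
robustness argument for gradient features presumes the dense cortical
structure of real brains, which gives every cell a strong structural
gradient for the bias to perturb only marginally; the phantom lacks
exactly that. The suite therefore asserts the direction-free property
that is true here — at maximum bias amplitude (0.5) the gradient
pipeline's leave-one-out accuracy falls strictly below its clean-condition
value — and the comparative claim is left to data with realistic
structure. The default amplitude (±10%) does not disturb the pipeline:
the 30+30 recovery experiment runs with that bias active.

## Known limitations

* The SVM wraps e1071/libsvm; exotic kernels, class weighting and
  probability calibration are deliberately out of scope.
* Threshold conversion assumes SUVR scales relate affinely; the package
  reproduces the published regressions and their composition, it does not
  validate that assumption.
* The descriptor assumes pre-registered, isotropic, skull-stripped input;
  no registration, resampling or segmentation is performed.
* Published cohort-level results (accuracies, AUCs, cohort mean SUVRs on
  clinical tracers) depend on restricted clinical data and proprietary
  template regions and are not reproducible by this package; nothing in
  the test suite claims them.
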
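---
title: "Stimulus information representation: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus information representation: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirep)
```

## The problem

In a Bubbles experiment an observer sees, on every trial, a sparse random
sample of a fixed ambiguous image and reports one of three perceptual
decisions ("the nuns", "Voltaire", or "don't know"). Simultaneously recorded
source-space neural activity gives, per trial, a voxel-by-time array. The
question this package addresses is how the high-dimensional stimulus
information is represented in the brain over time, and which parts of that
representation actually support the observer's behavior. The framework treats
this as a three-variable information problem — stimulus information samples,
neural activity, perceptual decision — instead of the usual two-variable
brain-stimulus or brain-behavior mappings.

The pipeline has six analysis stages, each usable on its own:

1. **Stimulus sampling** (`sf_decompose`, `generate_bubble_masks`,
   `compose_stimulus`, `downsample_masks`): the base image is split into six
   one-octave spatial-frequency (SF) bands with upper cutoffs 128, 64, 32,
   16, 8, 4 cycles/image; the first five bands are revealed through random
   Gaussian apertures (60 per trial in the reference design) and the constant
   sixth band is always added. Masks are analyzed at 64 x 64 resolution.
2. **Diagnostic features of behavior** (`binarize_visibility`,
   `diagnostic_map`): per-pixel visibility is binarized at 0.2 and related to
   the binary decision contrast (one percept vs. "don't know", the third
   percept excluded) by plug-in mutual information (MI), with a permutation
   maximum-statistic threshold.
3. **Brain features** (`reduce_activity`, `reduced_mi_images`, `nmf_basis`,
   `feature_coefficients`, `classify_features`, `kmeans_cosine`): MI images
   between pixel visibility and a reduced (component-by-time) activity matrix
   are factorized by non-negative matrix factorization (NMF); each feature
   image is thresholded at 15% of its maximum, L2-normalized, and scored per
   trial by a dot product with the trial's masks.
4. **Representation matrix** (`representation_matrix`): Gaussian-copula MI
   between each feature coefficient and the bivariate voxel state (amplitude,
   temporal gradient), for every voxel and time point, thresholded by the
   95th percentile of 200 permutation maxima.
5. **Dynamics** (`max_course`, `divergence`, `wavefront_regressions`,
   `junction`): per-voxel maximum-MI time courses over the diagnostic or
   nondiagnostic feature subset in 10 ms windows; onset/offset/duration per
   voxel; robust regressions of onset and duration against distance from the
   earliest-onset voxel; the junction as the latest offset among the farthest
   (top-quartile distance) nondiagnostic voxels; and a de-meaned dot-product
   divergence statistic with a shuffle null.
6. **Behavior representation** (`redundancy_matrix`,
   `representational_complexity`, `decision_mi`,
   `decision_specific_redundancy`): co-information redundancy per feature,
   voxel and time; per-voxel counts of redundantly represented features in
   five windows spanning 120-220 ms (the extended N/M170 course); and MI
   between voxel activity and the three-class decision.

## Estimation core

### Gaussian-copula MI

All continuous MI quantities use the Gaussian-copula estimator: each margin
is replaced by normal scores of its ranks, `qnorm((rank - 0.5)/n)` with
average ranks for ties, and MI is computed from the joint covariance of the
scores. This is a semi-parametric lower bound on the true MI: robust to
monotone marginal transforms (the estimate is invariant to them, which the
suite verifies to 1e-12) and parametric only in the copula. The analytic
small-sample bias correction (digamma terms in the Gaussian entropy
estimates) is applied by default, so null-distributed estimates scatter
around zero and may be slightly negative; they are stored as-is. Units are
bits everywhere, with a `units = "nats"` switch on the scalar estimators;
bias correction is likewise a visible flag rather than a buried constant,
since reported effect sizes depend on both conventions.

For mixed continuous-discrete pairs (`mi_gcd`) the estimator is the
difference between the marginal Gaussian entropy of the copula scores and
the class-weighted conditional entropies, each bias-corrected at its own
class size. Binary-visibility-by-binary-decision maps use the plug-in
contingency MI (`mi_discrete`); for two binary variables the copula route
and the plug-in route measure the same quantity, and the plug-in form is the
canonical choice for the diagnostic maps.

### Co-information

Redundancy among a feature coefficient F, voxel state M, and decision D is

    RED = MI(F; D) + MI(F; M) - MI(F; M, D)

Positive values mean the feature information in the activity overlaps the
feature information in behavior; negative values indicate synergy (the test
suite pins the sign on an XOR construction). The mixed joint term is
evaluated by the chain rule, `MI(F; M, D) = MI(F; D) + MI(F; M | D)`, with
the conditional term a class-weighted Gaussian-copula MI on globally
normalized scores. The three components are stored on every result so the
identity can be audited exactly; `redundancy()` also provides a plug-in path
for fully discrete variables, which the tests compare against enumeration
oracles on 2x2x2 tables.

### Permutation maximum statistic

Family-wise error control everywhere uses the maximum-statistic procedure:
shuffle the behavioral labels (or coefficients) across trials, recompute the
full statistic image, record its maximum, and threshold the observed image
at a percentile of the permutation maxima. The reference settings are 10000
permutations at the 99.9th percentile for the pixel maps (FWER p < 0.001)
and 200 permutations at the 95th percentile for the 3D matrices (FWER
p < 0.05); both are arguments, and simulation suites use smaller counts.
Percentiles throughout the package (null thresholds, feature classification,
junction distances) are computed by linear interpolation between order
statistics (`quantile` type 7), which keeps every threshold bit-reproducible.

## Design choices at genuinely open points

- **Band filters.** Only the octave cutoffs are fixed by the design; the
  filter family is not. The default is a raised-cosine transition in
  log2-frequency (quarter-octave half-width) arranged as an exact partition
  of unity, so the bands sum back to the image to machine precision and
  spatial ringing stays small; ideal annular filters are available via
  `filter = "ideal"`. The lowest band absorbs the residual low-pass content
  including the DC term, which is what makes the "constant sixth band"
  exactly the image mean for a flat image.
- **Aperture allocation.** The total of 60 apertures per trial is fixed, the
  per-band split is not. The default allocates counts proportional to
  1/sigma^2 (equal expected revealed area per band, the usual convention in
  this literature) with largest-remainder rounding toward the finest bands;
  the split is an argument.
- **Aperture combination.** Within a band, overlapping apertures combine by
  pointwise maximum (values stay in [0, 1] with 1 meaning full visibility);
  sum-then-clip is available. Aperture centers sit on the pixel grid, so a
  mask is exactly 1 at each center; border truncation is the default and an
  edge-padding option exists.
- **Binarization boundary.** Visibility exactly equal to 0.2 goes to the
  "no to low visibility" bin; the split is defined by strict inequality
  above the threshold, chosen for determinism and documented on
  `binarize_visibility`.
- **NMF.** The factorization is Lee-Seung multiplicative updates on the
  Frobenius objective with uniform random initialization under a fixed seed
  and best-of-restarts selection, since the update is monotone (tested) but
  can settle in local minima. The rank is either given or chosen by an elbow
  rule — the smallest k whose error improvement from one more component
  falls below 1%, capped at 25 (the reference analyses found 21-25
  components per observer) — evaluated on a row subsample with restarted
  fits.
- **Classification percentiles.** Features at exactly the 75th/25th
  percentile stay unclassified (strict inequalities); a feature passing both
  diagnostic rules takes the percept with the larger MI; diagnostic
  precedence over nondiagnostic is enforced with a warning.
- **Onset convention.** A voxel's onset/offset are the start times of the
  first/last significant 10 ms window. Nothing downstream depends
  qualitatively on the half-window shift this implies.
- **Robust regression.** "Robust linear regression" is implemented as
  iteratively reweighted least squares with a bisquare weight
  (`MASS::rlm`); p-values use the coefficient t statistic with n - 2
  degrees of freedom.
- **Divergence null.** The null shuffles the entries of the two voxel
  vectors independently by default (`shuffle = "joint"` applies one shared
  permutation; the difference was negligible in our simulations). The
  two-tailed Bonferroni bounds are computed from `alpha/(2 * n_windows)` —
  with alpha 0.05 and 40 windows, the 0.0625th and 99.9375th percentiles of
  the null.
- **Complexity windows.** "Five evenly distributed windows between 120 and
  220 ms" is implemented as five contiguous 20 ms windows; width and span
  are arguments. The median-across-observers summary is a separate utility
  (`median_complexity`) so single-observer runs stay first-class.
- **Group pooling.** Cross-observer analyses pool by simple concatenation
  (dynamics) or by indexing per-observer features onto a common spherical
  k-means basis (cosine distance, best of 1000 restarts by within-cluster
  cosine dissimilarity).

## The synthetic observer

Real recordings are not required anywhere: `ground_truth()`,
`simulate_trials()` and `simulate_activity()` generate a fully specified
observer with planted structure, and `recovery_report()` scores every
pipeline stage against that truth.

**Stimulus side.** Six planted templates: two compact high-SF "nun" faces in
band 1, a mid-SF eye in band 2 and a broad low-SF "Voltaire" face in band 3
(the diagnostic features), and two flanking nondiagnostic features in bands
2 and 3. Fine-SF templates use a plateau profile (support pixels carry
comparable evidence weight); coarse-SF templates keep a Gaussian profile
with a low support floor, since their bands' wide apertures spread evidence
into the tails regardless. Decisions follow a noisy evidence race: each
percept's evidence is the standardized visibility of its templates plus
Gaussian noise (SD 0.3 in evidence units), the best percept wins if it
clears a threshold, otherwise the response is "don't know". The threshold is
Monte-Carlo calibrated at construction time to a 25% don't-know target, the
rate the original task was controlled to; at 2000 trials the realized
fraction lands within a few percentage points of the target.

**Neural side.** 60% of voxels are wavefront voxels carrying one
nondiagnostic and one diagnostic feature each — so the two representations
share one spatial profile early, as in occipital cortex — with onsets
increasing at 1.2 ms/mm from a planted origin. Nondiagnostic offsets
collapse at the junction time (170 ms by default), diagnostic
representations are sustained to 380 ms. 10% of voxels form an integration
hub that accumulates the four diagnostic features with staggered onsets
(130-184 ms) and a common offset just before 200 ms, which places the
representational-complexity peak in the fourth of the five N/M170 windows.
The rest are pure noise. Amplitude is `gain x standardized coefficient x
kernel` plus unit-SD white noise (gain 1.5; kernel a half-cosine bump by
default, boxcar optional), and the gradient channel is the discrete
temporal derivative of the noisy amplitude.

**What the generator does not emulate.** Real source-localized MEG has
spatially correlated noise, 1/f spectra, leakage between nearby voxels,
trial-to-trial latency jitter, eye movements and learning across sessions;
decisions of real observers are not a fixed noisy template race. Passing the
recovery benchmarks therefore demonstrates that the estimators and the
inference chain are correct and well calibrated on data with the designed
structure — not that any specific neural finding would replicate in new
recordings.

## Problem sizes and numerical notes

The validation suite runs at desk scale, chosen so the full suite completes
in minutes while keeping every statistical property measurable: 64 x 64 x 5
masks throughout; 2000 trials for diagnostic-map recovery; 1500 trials, 500
voxels and an 8 ms activity grid for brain-feature recovery; 500 trials, 100
voxels and a 10 ms grid for the 20 junction/wavefront simulations; 500
global-null datasets of 500 trials at 32 x 32 x 5 for the family-wise error
calibration, which lands in [0.03, 0.08] at nominal 0.05. Voxel counts are
input dimensions, never constants: the reference dataset's 12,773-voxel
grid is simply a larger input.

Degenerate inputs are handled by convention, not silently: constant pixels
or activity columns yield zero MI where a zero-information answer is exact
(never-visible pixels), and explicit errors where the quantity is undefined
(constant copula margins, singular covariances — reported with the condition
number, classes with fewer than d + 2 trials). MI images destined for NMF
are clamped at zero after bias correction, since the factorization requires
nonnegativity.

## Reproducibility

Every stochastic function takes a `seed` argument and leaves the caller's
RNG stream untouched. `sir_run_all()` derives per-stage substreams from the
single configuration seed, writes each stage as an RDS file plus a manifest
of md5 hashes, and reruns byte-identically under a fixed configuration —
which the acceptance suite asserts. `resume = TRUE` reuses stage files
without recomputation and reproduces identical hashes.

## Known limitations

- The elbow rule for the NMF rank is a heuristic; on stacks whose error
  curve is dominated by a diffuse background it can under- or overshoot the
  planted dimensionality, which is why the rank is always overridable. At
  exactly the planted rank the Frobenius-optimal factorization can merge two
  compact low-energy features rather than split a diffuse high-energy one,
  so the recovery benchmark runs moderately over-complete (rank 8 for 6
  planted features, mirroring the reference analyses whose component counts
  exceed their distinct features) and scores the features matched to the
  planted templates; duplicates are tolerated, merges are not.
- The divergence statistic can flag weak late-window similarity when
  feature coefficients are correlated by sampling noise; at 500-600 trials
  this appears in a minority of seeds and the junction marker itself is
  unaffected.
- The Gaussian-copula estimator is a lower bound; strongly non-monotone
  dependencies would be underestimated. This matches its role here as an
  effect-size screen under permutation calibration.
- `mi_gcd` assumes within-class Gaussianity of the copula scores; heavily
  multimodal within-class structure would bias it.
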
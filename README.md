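# sirep

Stimulus information representation (SIR) analysis for perceptual decision
experiments: relate the visual information an observer saw on each trial, the
observer's perceptual decision, and source-space neural activity — as a
three-variable information problem rather than the usual two-variable
brain-stimulus or brain-behavior mapping.

The package is aimed at researchers running Bubbles-style reverse-correlation
experiments with time-resolved neural recordings (MEG/EEG source estimates),
and at methodologists who want the estimation core on its own.

## What it computes

For trials in which a base image is decomposed into one-octave
spatial-frequency bands and revealed through random Gaussian apertures:

- **Diagnostic features of behavior** — per-pixel plug-in mutual information
  between binarized visibility and a two-class decision contrast
  ("nuns" vs. "don't know"; "Voltaire" vs. "don't know"), with
  maximum-statistic permutation control of the family-wise error rate.
- **Brain features** — non-negative matrix factorization of MI images linking
  pixel visibility to a reduced activity matrix; each feature is thresholded
  (15% of its maximum), L2-normalized, scored per trial by a mask dot
  product, and classified diagnostic/nondiagnostic by percentile rules.
- **Representation matrix** — Gaussian-copula MI between each feature
  coefficient and the bivariate voxel state (amplitude, temporal gradient)
  for every voxel and time point: `MI(F; M)` over a feature-by-voxel-by-time
  grid, FWER-thresholded by permutation maxima.
- **Representation dynamics** — per-voxel max-MI time courses over feature
  subsets, onset/offset/duration, robust wavefront regressions of onset and
  duration against distance from the earliest-onset voxel, a de-meaned
  dot-product divergence statistic between diagnostic and nondiagnostic
  representations, and the spatio-temporal junction where the nondiagnostic
  wavefront collapses.
- **Feature redundancy with behavior** — the co-information

  `RED = MI(F; D) + MI(F; M) − MI(F; M, D)`

  for feature coefficient F, voxel activity M, and decision D, per feature,
  voxel and time; representational complexity (how many features a voxel
  redundantly represents with behavior in each of five windows spanning the
  extended N/M170 course, 120–220 ms); decision information in activity; and
  decision-specific redundancy per contrast.

All MI quantities use a rank-based Gaussian-copula estimator (bits, analytic
small-sample bias correction), `RED` stores its three components so the
defining identity is auditable exactly, and every significance threshold
comes from the permutation maximum-statistic procedure.

A fully specified synthetic observer (`ground_truth()`,
`simulate_trials()`, `simulate_activity()`) provides planted templates, a
calibrated noisy evidence-race decision rule, and encoding voxels with a
planted wavefront, junction and feature-accumulation hub — so every stage is
testable by parameter recovery (`recovery_report()`) without any real
recordings.

## Worked example

```r
library(sirep)

## a synthetic observer with a planted 170 ms junction
truth <- ground_truth(n_voxels = 100, time_ms = seq(0, 400, 10), seed = 1)
trials <- simulate_trials(truth, 1000, seed = 2)
activity <- simulate_activity(truth, trials, seed = 3)
trials
#> Synthetic trials: 1000 trials, 20480 pixels/trial
#>   decisions: nuns=398 voltaire=342 dont_know=260

## diagnostic features of the "Voltaire" decision
vis <- binarize_visibility(trials$masks)
map <- diagnostic_map(vis, trials$decisions, "voltaire", n_perm = 1000, seed = 4)
map
#> Diagnostic map (voltaire vs. don't know): 602 trials, 20480 tests
#>   FWER threshold 0.03078 bits (99.9% of 1000 permutation maxima); 588 significant

## representation dynamics over the true feature basis
feats <- truth$templates / sqrt(rowSums(truth$templates^2))
coefs <- feature_coefficients(trials$masks, feats)
rmat <- representation_matrix(coefs, activity, n_perm = 200, seed = 5)
rmat
#> Representation matrix: 6 features x 100 voxels x 41 time points
#>   FWER threshold 0.01688 bits (95% of 200 permutation maxima); 2394 significant cells

nondiag <- max_course(rmat, which(!truth$feature_meta$diagnostic),
                      subset = "nondiagnostic")
junction(nondiag, coords = activity$coords)
#> Junction: 15 far voxels, temporal marker 170 ms

## redundancy with behavior over the extended N/M170 window
red <- redundancy_matrix(coefs, activity, trials$decisions,
                         which(truth$feature_meta$diagnostic),
                         n_perm = 200, seed = 6, times_ms = seq(120, 220, 10))
representational_complexity(red)
#> Representational complexity: 100 voxels x 5 windows; per-window totals: 52, 69, 82, 100, 90
```

Reading the output: 26% of trials end as "don't know" (the rule is calibrated
to 25%); the Voltaire map flags 588 of 20,480 pixel-band tests at FWER
p < 0.001, concentrated on the planted low-SF face; the junction marker
recovers the planted 170 ms collapse of the nondiagnostic wavefront exactly;
and the per-voxel feature counts peak in the fourth 20 ms window (180–200 ms),
where the planted integration hub accumulates all four diagnostic features.

`sir_run_all(sir_config(...), out_dir)` chains every stage (simulation →
diagnostic maps → brain features → representation matrix → dynamics →
redundancy/complexity → recovery report), writing one RDS file per stage, a
config YAML, and a manifest with md5 hashes; reruns under a fixed
configuration are byte-identical, and `resume = TRUE` restarts from the
stage files.

The methods vignette (`vignettes/sir-methods.Rmd`) documents the estimators,
the permutation procedures, the synthetic observer's design, and every
convention chosen at points the analysis leaves open.

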
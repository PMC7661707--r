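---
title: "Methods: radiomic and spectroscopic classification of glioblastoma therapy response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic and spectroscopic classification of glioblastoma therapy response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioresponse)
```

## The problem

Preclinical glioblastoma studies follow therapy response noninvasively with
two MR modalities acquired on the same animals: T2-weighted images (with a
manually segmented tumor mask) and MRSI grids, where each voxel of a 10x10 or
12x12 grid registered onto the image carries a metabolite spectrum on a
chemical-shift (ppm) axis. The task is a two-class decision per subject —
treated (responding) versus control — produced by linear classifiers on
features extracted from each modality, fused across slices or voxels, and
visualized as an anatomically registered certainty map. Because subjects may
contribute one to four slices and several hundred voxels, all
cross-validation in this package is grouped by subject.

## Radiomic description of a masked slice

Each slice yields 90 features:

* **42 texture statistics** on the tumor bounding box (the smallest
  axis-aligned rectangle containing the mask, half-open convention),
  quantized to 32 equal-width gray levels: 11 GLCM statistics (energy,
  contrast, correlation, variance, homogeneity, sum average, entropy,
  dissimilarity, autocorrelation, cluster shade/prominence), 13 GLRLM and 13
  GLSZM run/zone statistics (the classical Galloway/Thibault sets: short/long
  emphasis, gray-level and length nonuniformity, percentage, low/high
  gray-level emphases and their four combinations, gray-level and length
  variances), and 5 NGTDM statistics (coarseness, contrast, busyness,
  complexity, strength). GLCM and GLRLM are averaged over the four distance-1
  directions; GLSZM zones are 8-connected. The full manifest counts 42 and is
  enforced by test; it can be swapped for another manifest if the canonical
  list ever needs to change.
* **48 Minkowski functionals**: 16 thresholds equally spaced (endpoints
  included) over the intensity range *inside the mask*; for each binary
  object `mask & (image >= t)` the area (pixel count), perimeter (4-neighbor
  foreground/background edge count, exact integer; the mask exterior counts
  as background) and Euler number (8-connected objects minus 4-connected
  holes, computed by 2x2 quad-pattern counts).

Choices worth knowing: texture statistics see the full bounding-box rectangle
(including non-tumor pixels), Minkowski functionals see only the mask — both
follow how the rectangle step and the mask thresholds are described in the
underlying method. A constant ROI is well defined (energy 1, contrast and
entropy 0). All 90 features are translation invariant and finite by
construction.

## Convex NMF of MRSI spectra

Only voxels whose full pixel block lies inside the tumor mask enter the
spectral pipeline. Pooled tumor spectra `X` (n rows, L points) are factorized
as `X ~ G F` with `F = t(W) X`: each source is a nonnegative combination of
observed spectra (`W >= 0`) and each spectrum a nonnegative mixture of
sources (`G >= 0`), while the data themselves may contain (small, noise-born)
negative values. Fitting uses the standard multiplicative updates on the Gram
matrix split into positive and negative parts, initialized from k-means
cluster indicators (seeded; random fallback), with `tol = 1e-6` relative
error change and `max_iter = 500`.

**Numerical note.** Multiplicative updates converge sublinearly near a fix
point (measured on an exactly factorizable fixture: relative error 2.8e-3
after 500 iterations, 1.4e-4 after 10^4). The fit therefore ends with up to
five *polish* rounds: refit `W` by nonnegative least squares toward the
least-squares-optimal sources for the current `G`, then refit `G` row-wise by
NNLS; a round is kept only if the reconstruction error decreases, so the
error trace is non-increasing end to end and exactly factorizable data reach
machine precision. Large fits (n > 400) polish only `G` by default, which is
cheap and leaves the error monotone.

New spectra (holdout voxels) are projected onto fitted sources by NNLS
(Lawson-Hanson active set) — the default avoids any train/holdout leakage;
`paper_mode = TRUE` reproduces the original joint fit on all spectra.
Recovered sources are compared to references by maximum-weight bipartite
assignment on cosine similarity, which resolves the factorization's
permutation/scale ambiguity in every recovery test.

## Feature selection

Three schemes, all restricted to linear models:

* **Filter**: Welch two-sample t per feature, ranked by |t| (zero-variance
  features score 0 and rank last; ties break by name).
* **Embedded RFE**: K linear models are trained on the training sides of K
  grouped stratified folds; the relevance of feature i is the mean of
  |w_ij| over the models, and the least relevant feature is removed each
  step. Features are z-scored inside the model fit (training statistics), so
  weight magnitudes are comparable — the comparison is meaningless on raw
  scales.
* **Wrapper RFE**: each step evaluates the grouped-CV accuracy with every
  single remaining feature removed and eliminates the feature whose removal
  scores highest; ties break by lower univariate |t|, then name. All
  single-feature removals are evaluated (the cheaper heuristic alternative
  was rejected for determinism and transparency).
* **Hybrid**: embedded RFE keeps the top `m = 30` features, then the wrapper
  refines within them — the scheme for the 32-subjects-to-90-features MRI
  setting, where a plain wrapper cannot distinguish features early on.

All RFE outputs are nested by construction: the subset of size m is contained
in every larger subset.

## Classification, voting, certainty

Linear models: logistic regression (L2-penalized Newton, C = 1, intercept
unpenalized), LDA (pooled covariance with a small stabilizing ridge, prior
log-odds in the intercept) and a linear SVM (L2-regularized squared hinge,
C = 1, solved by BFGS from the zero start — smooth, deterministic). Labels
are fixed package-wide as control = -1, treated = +1; a decision score of
exactly zero maps to treated. CV protocols: leave-one-subject-out for the MRI
table, 20-fold grouped by subject for the voxel table (capped at the number
of training subjects on small cohorts).

Subject fusion:

* **SVS** (slices): weighted mean of binary slice responses, weights = tumor
  mask pixel counts; label treated iff the fused value >= 0.5 (ties treated).
* **VVS** (voxels): unweighted majority over all classified voxels of the
  subject, pooled across slices; fused value = fraction voting treated; ties
  treated. The tallies feed the top bar of the rendered map.

Per-voxel certainty uses the piecewise posterior of the positive class
computed from training scores: 0 below the maximum control-class score, the
positive-class prior within the (inclusive) band between the maximum control
and minimum treated scores, and 1 above. That formula is only well defined
when training scores separate; with overlap the band collapses and the
calibration falls back to a Platt-style sigmoid (logistic regression of the
class on the score), which is continuous and monotone. Which path applied is
recorded per calibration. The rendered map shows the certainty of the
*predicted* label (dark = unreliable regardless of class), red contours on
misclassified voxels, a bottom bar for the true class and a top bar split by
the predicted voxel percentages.

## The synthetic cohort: what it emulates and what it does not

No raw data are deposited for the reference cohort, so every stage is
validated against a seeded generator that reproduces the *statistical
structure* the analysis assumes:

* 29 control / 34 treated subjects by default; training subjects single-slice
  and holdout subjects multi-slice (2-4), assigned stratified-randomly by
  `holdout_fraction` (about half, mirroring the 32/31 split).
* images: a brain ellipse with a hyperintense tumor ellipse; treated tumors
  receive 4-12 seeded hypointense foci (the minimal mechanism that makes
  texture and Minkowski features class-informative), controls at most one
  faint focus; Gaussian pixel noise and a 3x3 blur.
* spectra: in-tumor voxels are `amplitude * (h %*% profiles) + N(0, noise_sd)`
  with `h >= 0` drawn from a class-dependent Dirichlet; out-of-tumor voxels
  carry a distinct NAA/Cr/Cho "normal tissue" profile. Ground-truth sources
  are unit-maximum sums of Lorentzian peaks at fixed metabolite positions
  (Lac 1.33, Ala 1.47, Glx 2.1/2.4, PUFA 2.8 ppm, ...), source 1 PUFA/Lac-rich
  (the post-treatment pattern), source 2 Glx/Ala-rich (untreated). The ppm
  axis is descending and stored explicitly. Spectra are emitted on the
  unit-maximum intensity scale of the profiles (the original normalization
  pipeline is not public; this convention is recorded with the data).
  `noise_sd = 0.05` (5% of unit peak amplitude) by default.

**Class mixing and identifiability.** The default concentrations
(`default_class_mixing()`: 2 for the class-typical source, 0.2 for the other
class's source, 0.4 for shared sources) are deliberately sparse: most voxels
are dominated by one tissue pattern, a minority by one of the shared
patterns. This is the regime in which the factorization's sources act as
representative signal centroids — and it is also a mathematical requirement:
convex-NMF sources live in the cone of observed spectra, so a ground-truth
source is recoverable only if some voxels are nearly pure in it. An earlier
default with dense mixtures (shared concentration 1.5) capped best-match
cosines for the shared sources at ~0.85 for every seed and iteration budget;
the revision to sparse mixing was made after observing that failure, for the
identifiability reason above, and is disclosed in the project ledger.

What the generator does **not** emulate: acquisition physics, field
inhomogeneity, baseline/phasing artifacts, realistic anatomy, partial-volume
effects at mask edges, or the original cohort's effect sizes. A green
end-to-end test therefore establishes that the pipeline is correct and
self-consistent on data with known structure — not that the original
accuracies are reproduced (those are explicitly out of scope).

## Degenerate inputs and tie rules (summary)

Empty mask: error naming the slice. Constant ROI: level 1, defined feature
limits. Zero variance in both classes: |t| = 0, ranked last. Single-class
training fold: stratified folds are drawn by class, so this only occurs on
degenerate inputs, where it is an error. Fused value exactly 0.5: treated.
Score exactly 0: treated. Calibration band edges: inclusive (the prior
applies at both boundaries).

## Runtime choices in the test suite

The suite regenerates everything from code. Unit and acceptance tests run on
a 12-subject, 64-pixel, 128-point cohort (structure identical to the
default), which keeps the complete suite under ~2 minutes on one CPU;
the permutation-null criterion reuses a single unsupervised factorization
across the 20 label permutations because the fit never sees labels. The
paper-scale cohort (63 subjects, 256-pixel images) is available behind
`cohort_spec()` defaults and the CLI `--full` flag.

## Known limitations

* The exact 42-statistic manifest of the original toolbox is in a
  supplementary file that is not public; the manifest here is the classical
  choice with the same counts per matrix and is declared in code.
* Convex NMF recovers only sources that are nearly pure in some voxel (see
  above); model-order selection for K is out of scope.
* The wrapper RFE is O(p^2) CV evaluations; for the 90-feature MRI table use
  the hybrid scheme (that is what it is for).
* Rendered PNGs are deterministic for a fixed libpng, but only the map *data*
  are asserted bit-stable across platforms.
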
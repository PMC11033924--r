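---
title: "Functional-gradient analysis of parcellated connectivity: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-gradient analysis of parcellated connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradmap)
```

## The estimator

`gradmap` estimates cortical functional gradients from a subject's
parcellated functional-connectivity (FC) matrix. The chain is:

1. Pearson correlations between all P parcel time series; Fisher
   r-to-z transform with the diagonal set to zero (the self-correlation maps
   to infinity and must never survive sparsification).
2. Per-row sparsification: in each row the `k = round(density·(P−1))`
   largest entries *by signed value* are kept (density 0.10, so k = 20 at
   P = 200). Ties break by parcel index; the result is deliberately
   asymmetric, as each parcel keeps its own strongest partners.
3. Cosine affinity between sparsified rows, negatives clipped to zero —
   similarity of *connectivity profiles*, not of raw signals.
4. Diffusion-map embedding: with `D` the diagonal of affinity row sums,
   `W' = D^{-α} W D^{-α}` (α = 0.5, the anisotropic normalisation that
   removes first-order density effects), `M = D'^{-1} W'`, and the
   non-trivial eigenvectors of `M` — computed through the symmetric
   conjugate `D'^{1/2} M D'^{-1/2}`, which keeps the solver symmetric and
   the spectrum real. With `diffusion_time = 0` (the default) components are
   scaled by the multiscale factor `λ/(1−λ)`; a positive diffusion time `t`
   scales by `λ^t` instead.
5. A group template is built from the *mean Fisher-z* matrix of all
   subjects (the z-transform precedes gradient estimation, so averaging
   happens on the z scale), with each component's sign fixed so that its
   largest-magnitude entry is positive.
6. Every subject's embedding is rotated onto the template by orthogonal
   Procrustes — the closed-form `R = UVᵀ` from the SVD of `XᵀT`; rotation
   and reflection only, no scaling or translation. All 10 retained
   components are aligned jointly (a 2-component alignment is possible but
   rotations estimated from 10 components are more stable); analysis then
   uses columns 1–2.

Explained variance is reported as `λ_c / Σ λ` over the retained non-trivial
eigenvalues. This is a declared convention: diffusion-map eigenvalues admit
no unique variance decomposition, and reported percentages are comparable
only under the same convention.

Gradient values have arbitrary units; only relative positions are
meaningful. This has a consequence worth stating plainly: the embedding is
*relational*. A connectivity change planted in one network moves other
parcels' aligned coordinates too, because every coordinate is defined
relative to the whole similarity structure. Tests of localisation must
therefore expect diffuse secondary effects around a planted primary one.

## Network metrics

Given an aligned embedding and a parcel-to-network lookup (7 canonical
networks by default):

* **within-network score** — mean gradient value per network, per gradient;
* **within-network dispersion** — the sum of squared Euclidean distances of
  the network's parcels from their centroid in the 2-D (G1, G2) plane;
* **between-network dispersion** — Euclidean distance between network
  centroids in that plane;
* **global gradient variation** — the sample standard deviation
  (denominator P−1; the spec of the denominator is a package convention) of
  each gradient over all parcels. Lower variation on an axis means the
  hierarchy is *compressed*.

Centroids are unweighted means; networks of different sizes are not
reweighted. Dispersion and between-network metrics are invariant to a
common rotation of the gradient plane; the per-axis scores and variations
are equivariant, which is why subjects must be aligned before comparison.

## Group statistics

Regional and network score comparisons use a multivariate linear model on
the bivariate (G1, G2) response with intercept, group indicator and
covariates (age, sex, mean framewise displacement; sex coded 0/1 by first
appearance). The group effect is tested with the Hotelling–Lawley trace for
the single-row contrast selecting the group coefficient,
`T² = ν·tr(H E⁻¹)` with `ν = n − p`, and the transform
`F = T²(ν−q+1)/(qν)` on `(q, ν−q+1)` degrees of freedom, which is exact for
a rank-one hypothesis. Dispersion and variation metrics use the analogous
univariate model with a two-sided t-test. Bonferroni families follow the
natural unit counts: 200 parcels, 7 networks, 7 dispersions, 21 pairs, 2
gradients; the correlation screen corrects over (features × variables) by
default, with the family size exposed in the call because different screens
legitimately define it differently.

Spearman correlations use average ranks, a t-approximation for the p-value
and the Fisher-transform 95 % interval `tanh(atanh ρ ± 1.96/√(n−3))`; the
rank-based variance inflation (1.03×) is available through `ci_inflation`.
Missing clinical values are handled by pairwise deletion with the per-pair
n reported.

## Prediction

The cognition score is predicted from the 14 within-network scores with
gradient-boosted trees. The design guards against the two classic leaks:

* a single 80/20 hold-out split (`ceiling(0.2·n)` held out) is drawn once
  and never touched during training, hyperparameter search or feature
  selection; the 10 repetitions re-draw only the CV folds;
* feature selection is performed inside the outer loop: hyperparameters are
  chosen by an inner five-fold grid search (depth {2,3,4} × learning rate
  {0.05,0.1,0.3} × rounds {50,100,200} — a small grid spanning the
  bias-variance range), importance gain is averaged over outer folds, and
  models restricted to the top-n features (n = 1…14) are compared on outer
  validation folds; the smallest n wins ties.

Permutation significance shuffles the training targets and reruns the whole
ranking-and-selection procedure per permutation. To keep 1000 permutations
tractable the permutation path skips the inner grid search and reuses the
hyperparameter configuration most frequently selected across the observed
outer folds (recorded in the result as `permutation_grid`), so the null
models mimic the complexity actually chosen on the real targets; the full
grid can be forced by passing it as `perm_grid`. The observed error entering
the comparison is recomputed by the identical reduced procedure — comparing
a grid-searched observed value against single-configuration nulls would
bias the test — and the observed mean over repetitions is compared against
single-run nulls, which is mildly conservative (the averaged statistic has
the smaller sampling variance).

Near-flat error curves over n are common with a single strong predictor:
selection then picks whichever n is marginally best, so a "perfect
predictor" is guaranteed to be ranked first and included, but not
necessarily to be the *only* selected feature.

## The synthetic cohort

The generator exists so that every downstream stage has a ground truth. A
subject's P = 200 parcels (7 networks with canonical sizes, 240 timepoints
at TR = 1.5 s) are drawn from a zero-mean Gaussian with correlation matrix
`Σ = ΛΛᵀ + ψI`, rescaled to unit diagonal, where Λ stacks:

* a global factor and 7 network factors producing within/between network
  correlations 0.35/0.05 (`ψ = 1 − 0.35`, so with the axes switched off the
  matrix is exactly the block model);
* a **baseline "hubness" column** (strength 1.2, within-network spread
  0.6): every parcel carries a shared positive factor of smoothly varying
  amplitude. Hub parcels correlate with everything;
* two **centred axis-contrast columns** (strengths 0.6 and 0.5): each
  parcel has a deterministic position on a visual↔sensorimotor axis and a
  sensory↔transmodal axis, from per-network anchors plus within-network
  ramps/waves. The attention networks are given wide within-network spread
  (they are spatially heterogeneous), the primary sensory networks compact;
* **local-neighbourhood bump columns** (strength 0.1, scale 3 parcels)
  emulating the spatial autocorrelation of connectivity profiles.

The hubness and neighbourhood columns are not decoration: under top-10 %
row sparsification a pure block model with blocks larger than k = 20 is
*provably disconnected* (each row fills its k slots within its own block),
whereas real connectomes stay connected through hub regions and spatially
overlapping profiles. They also keep the leading Markov eigenvalues away
from 1, where the multiscale `λ/(1−λ)` scaling would amplify per-subject
eigenvalue jitter into large metric noise.

Planted patient effects:

* **sensorimotor hierarchy disruption** — patients' sensorimotor axis-1
  loadings are pulled toward the hierarchy centre by 0.6 (the network loses
  its polar position, consistent with disrupted sensory segregation);
* **secondary-axis compression** — the whole axis-2 column is multiplied by
  0.7;
* **latent cognition coupling** — each patient's default-mode axis-2
  entries are scaled by `δ ~ N(1, 0.4)`, and the cognition score is
  generated *from δ alone* (`38.8 + 25(δ−1) + N(0, 4.5)`, giving a score
  mean ≈ 39 and SD ≈ 11 points). Because the score is tied to the
  generative parameter and not to any downstream gradient quantity,
  recovering the score–gradient association is a genuine end-to-end test.

Covariates are drawn to resemble a clinical MS cohort (patient age
37.6 ± 9.9, control 38.1 ± 12.0 years; female fractions 84/122 and 56/97;
mean FD lognormal with median ≈ 0.096 mm) and are independent of the signal
by default, so covariate-adjusted tests are calibrated under the null.
EDSS, disease duration, lesion load and brain parenchymal fraction are
generated independent of everything and serve as null variables for the
correlation screen.

Effect magnitudes and the geometry were fixed once during generator design,
by checking at the population level (noise-free covariance) and on pilot
cohorts that the planted effects are expressed where intended — the pull
direction matters, for instance: pulling the sensorimotor network *inward*
cooperates with the global compression, whereas pushing it outward partly
cancels the compression's variance signature through the relational
embedding — and they have not been revisited since. Default sample sizes
are 60 patients + 60 controls.

What the generator does **not** emulate: hemodynamics and temporal
autocorrelation (signals are temporally white by default; an AR(1) option
exists), motion artefacts and their coupling to FD, scanner noise spectra,
lesions, and the empirically observed ordering/swapping of the first two
gradients in real cohorts — axis identity is whatever the planted
covariance produces. Passing recovery tests on these cohorts therefore
demonstrates the pipeline's correctness and sensitivity under the assumed
generative model, not performance on real fMRI.

## Numerical choices and degenerate inputs

* Sparsification keeps signed values; `density·(P−1) < 1` is an error.
* All-zero sparsified rows (a parcel with no retained connections) are an
  error naming the parcel; upstream QC should have removed it.
* Disconnected affinity graphs raise an error listing component sizes
  rather than silently embedding one component.
* Retained eigenvalues ≤ 0 or ≥ 1 (numerically disconnected or degenerate
  kernels) are errors, not warnings.
* The band-pass filter is a zero-phase (forward–backward) Butterworth of
  order 2 per pass; series are demeaned first, since the band has no DC
  response and demeaning shortens edge transients. Confound regression is
  exactly idempotent; repeated band-pass filtering is not (no realisable
  filter is), but leaves in-band content essentially unchanged.
* Confound regression before filtering, in that order; both stages are
  optional so that temporally white synthetic cohorts can skip them.
* QC uses a strict inequality (mean FD > 0.5 mm excludes, exactly 0.5 is
  retained) and never reorders retained subjects.

## Problem sizes used by the validation suite

The packaged checks run at the study's native scale where that is cheap
(200 parcels, 240 timepoints, 60+60 subjects) and use 100 replicate
cohorts for recovery rates, 2000 null simulations for test calibration,
and 200 permutations for the prediction significance — sizes chosen to
keep Monte-Carlo error far below the decision margins at modest runtime.

## Known limitations

* Procrustes alignment has no scaling step, so per-subject differences in
  overall embedding magnitude (partly driven by eigenvalue jitter) remain
  in the aligned coordinates and inflate metric variance.
* The relational nature of the embedding means planted localised effects
  produce diffuse significant secondary effects; "all significant parcels
  lie in the planted network" is not an attainable criterion at any useful
  effect size, and the suite instead checks that the top-ranked effects are
  in the planted network.
* The explained-variance convention (share of retained non-trivial
  eigenvalues) makes percentages depend on `n_components`.
* With correlation-normalised (unit-diagonal) inputs, "compression" of an
  axis is only identifiable relative to the remaining structure; absolute
  variance changes are not recoverable from correlation matrices.
* The permutation test of the prediction error has limited power at small
  cohort sizes: with 60 patients and a 20 % hold-out, 48 training subjects
  remain, the boosted-tree models extract only part of even a strong
  network–cognition coupling, and single-run permutation nulls are widely
  spread — so `p ≤ 0.05` is reached in only about half of cohort
  realisations at the default effect sizes, even when feature selection and
  direction-of-influence recover the planted link essentially always. Rank
  correlation screens are substantially more powerful than the permutation
  test at this scale.
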
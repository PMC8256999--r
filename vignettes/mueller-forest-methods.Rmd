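---
title: "Methods: polarimetric simulation and Gini-forest classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polarimetric simulation and Gini-forest classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muellerforest)
```

## The measurement model

A sample's polarization transfer is modeled as a single 4×4 Mueller matrix
`M` acting on Stokes vectors, `S_out = M Ŝ`. The package adopts the
convention that `s3 > 0` is right-handed circular light, with the six probe
states `LIN0 = (1,1,0,0)`, `LIN45 = (1,0,1,0)`, `LIN90 = (1,−1,0,0)`,
`LIN135 = (1,0,−1,0)`, `RHC = (1,0,0,1)`, `LHC = (1,0,0,−1)`.
`reconstruct_mueller()` recovers `M` exactly from the six noiseless outputs
by componentwise sums and differences; each reconstruction column depends
only on its own state pair, which the test suite checks as an invariant
together with the round trip `reconstruct(measure(M)) = M` to 1e−10 over
random composed matrices.

Working with a single matrix deliberately avoids polar (Lu–Chipman-style)
decomposition as an *analysis* output: decomposition presumes a sequential
ordering of dichroism, retardance and depolarization that real tissue does
not guarantee. The classifier therefore consumes the raw normalized
elements. Features are the 16 elements divided by `m11` with `m11` dropped,
in fixed row-major order (`m12, m13, m14, m21, …, m44`); the ordering is a
package convention (any fixed one would do) so that CSVs and serialized
models interoperate. Normalization makes features invariant to overall
intensity scale, so no radiometric calibration is modeled; how a blank
reference slide would enter the measurement (multiplicatively or
subtractively) is an instrument question the package does not take a
position on.

Reconstructed matrices from noisy data can be mildly unphysical
(`|m_ij| > m11`); these are warned about, never rejected, because rejecting
them would bias the feature distributions that the classifier is meant to
see.

## The synthetic campaign

Real labeled tissue measurements are not publicly available, so the
generator is a first-class, tested component whose job is to emulate the
*statistical structure* of such a campaign, not any particular tissue's
optics.

**Composition.** Each sample's matrix is `M = M_Δ · M_R · M_D`: a diagonal
depolarizer `diag(1, a, b, c)`, an elliptical retarder (linear retardance
`δ` at fast axis `θ_R`, then optical rotation `ψ`), and a diattenuator with
diattenuation vector `(d cos 2θ_D, d sin 2θ_D, cd)`. The order is the
conventional forward polar-decomposition order; since the generator only
needs to produce physically valid matrices with `m11 = 1`, any fixed valid
order would serve, and this one keeps every factor invertible for testing.

**Class means.** The four classes' mean parameters are artifact choices:
melanoma is strongly depolarizing (`a,b,c ≈ 0.15–0.35`, melanin-like), the
carcinomas intermediate with larger retardance (collagen remodeling), and
normal skin weakly depolarizing. They were chosen once so that (i) element
magnitudes are similar across classes while distributions differ, and (ii)
the within-slice variability bands below are met; they carry no claim of
biological fidelity. `default_tissue_specs(separation)` interpolates every
class mean towards the grand mean, giving a matched chance-level control at
`separation = 0`.

**Hierarchy.** Parameters are drawn per sample (sd ≈ 0.03–0.08 per
parameter), perturbed per slice (a quarter of the sample spread), and each
measurement point adds Stokes-level noise. The training/testing split is by
*sample* — one held-out sample per class — so the test partition measures
generalization to unseen samples, not unseen points. Default layouts
reproduce the study design exactly: 607 training vectors
(282 BCC / 231 SCC / 52 melanoma / 42 normal) and 62 testing vectors
(30/23/3/6). The published slicing protocol (4–6 slices × 4–6 points)
cannot decompose some of those totals, so a few layouts use 3–6 slices or
points; totals take precedence.

**Noise model.** Noise enters at the Stokes level, before reconstruction.
For each reconstruction pair of states, each Stokes component receives a
*common-mode* draw (added to both outputs) and a *differential* draw (added
to one, subtracted from the other). Reconstruction sums/differences the
pair members, so the common channel of the LIN0/LIN90 pair feeds column 1
and the differential channels feed columns 2–4 — every element's
repeat-point spread is independently settable. Purely independent
per-output noise cannot do this: `m21` and `m22` both derive from component
2 of the same two outputs and would be forced to equal spreads. The
defaults (`sigma_wide = 0.055`, `sigma_narrow = 0.004`) place the heavy
channels so that the mean within-slice standard deviation lands in
0.03–0.1 for `m12, m13, m14, m21, m24, m34` and below 0.01 for the other
nine elements, the qualitative picture expected of scattering tissue where
circular-state elements are perturbed most (helicity flipping) and
intensity-coupled terms drift. `calibrate_noise_bands()` verifies the bands
on any generated dataset. `sigma_wide` sits near the geometric middle of
the band so the check is not knife-edged; the small narrow-channel sigma
also bounds the `m11` normalization cross-talk (each feature inherits at
most `|m_ij| · sigma_narrow` extra spread from dividing by a noisy `m11`).

**What passing tests do not show.** The generator emulates counts,
hierarchy, noise bands and class-distinct distributions; it does not
emulate real element distributions (no public data exists to match), outlier
structure, instrument drift, or wavelength dependence. A classifier that is
perfect here says the pipeline is correct and the campaign separable — not
that real BCC/SCC lesions separate this cleanly; the published experience is
that they partially confuse.

## The classifier

CART trees are grown greedily: at each node a fresh random subset of
`mtry = floor(sqrt(15)) = 3` features is drawn (the standard forest
default; the subset size is otherwise unspecified in the workflow this
reproduces), candidate thresholds are the midpoints of consecutive distinct
sorted values of each candidate feature, and the split maximizing the
sample-proportion-weighted Gini decrease
`n_ij = w_j G_j − w_L G_L − w_R G_R` is taken. Growth stops at purity,
`max_depth` (root split = depth 1), node size `< min_samples_split = 2`, or
when no split has positive decrease. Ties in the best split resolve to the
lowest feature index, then the lowest threshold; plurality ties in voting
resolve to the first class level, with levels ordered case-insensitively
(`BCC < melanoma < normal < SCC`) independent of locale. Each tree trains
on a bootstrap resample of size n with replacement. Vote *fractions* (votes
/ trees), not averaged leaf posteriors, are the ROC scores — the ensemble
is described as a poll, and fractions are its native score.

Importance follows the impurity-decrease decomposition: per tree,
`f_i = Σ_j n_ij / Σ_k n_ik` over internal nodes; `F_i` is the mean of `f_i`
over trees, renormalized to sum to 1 (a tree with no internal node
contributes zeros). Importance is invariant to consistently scaling a
feature by a positive constant, since thresholds scale along with the data.

Deployment hyperparameters default to 220 trees of depth ≤ 14, the
operating point of the workflow the package reproduces; `grid_search()`
scans `ntree ∈ {10, 20, …, 1000} × depth ∈ {2, …, 20}` by repeated
cross-validated accuracy for users who want to re-derive them.

## The training workflow

Class imbalance (282 vs 42 training vectors) is handled by random
duplication of minority-class instances until all classes match the
majority count. Two methodologically questionable choices are *kept on
purpose* because the reproduced workflow made them, with flags to opt out:
oversampling happens **before** fold splitting, so duplicates of one
instance can land in different folds and inflate validation accuracy; and
the test partition is **also** oversampled (30 per class), which reweights
but does not add information. `run_pipeline(oversample_test = FALSE)` and
`train_final(balance = FALSE)` disable them, and the pipeline warns when
the faithful behavior is active.

Cross-validation is stratified 10-fold with 3 repetitions under derived
seeds; scoring is plain accuracy (the workflow reports training/validation
accuracy, so grid search is scored the same way, by CV mean across the
repeated folds — whether the original search sat inside or outside the
repetition loop is unstated, and CV-mean scoring is the conventional
reading). Grid-search ties resolve to fewer trees, then smaller depth, so
results are invariant to grid ordering.

## Numerical and reporting conventions

* Reported metrics round to two decimals, **half away from zero**, so
  111/120 = 0.925 prints as 0.93 and 30/32 = 0.9375 as 0.94; raw values are
  always retained in machine output.
* Zero-denominator precision/recall is reported as 0 with a warning.
* One-vs-rest AUC uses thresholds at the distinct observed scores and
  trapezoidal integration, which equals the Mann–Whitney pairwise
  probability with ties counted 1/2 (checked against both a brute-force
  pairwise oracle and an independent ROC implementation); a class absent
  from the truth has undefined AUC, reported `NA` and dropped from the
  unweighted mean with a warning.
* All randomness flows from explicit integer seeds; fits, campaigns and
  report files are reproducible byte for byte under a fixed seed.

## Problem sizes and controls

The test suite exercises the full 607/62 campaign where the counts
themselves matter and a reduced ~200-vector campaign (four samples of three
slices per class) elsewhere; forests in unit tests use 10–100 trees, with
the 220-tree deployment fit exercised end to end in the acceptance checks.
For the zero-separation control, points within a held-out sample are
strongly correlated, so the *sample* is the effective unit of the accuracy
estimate; `chance_level_config()` therefore widens the held-out panel to 40
samples per class (standard error ≈ 0.035) instead of judging chance from
the default 4 held-out samples. The label-permutation control shuffles test
labels against fixed vote fractions and averages the mean AUC over 60
permutations.

## Known limitations

* The simulator's class geometry is favorable; real campaigns show partial
  BCC/SCC confusion that the defaults do not reproduce.
* No out-of-bag error, permutation importance, pruning, categorical
  features, SMOTE-style synthesis, or nested cross-validation — all outside
  the reproduced workflow.
* Depolarization is modeled as diagonal in the Stokes basis; anisotropic
  depolarization and polarizance cross-terms are not generated.
* The forest is single-threaded, pure R; it is sized for 10³-instance
  campaigns, not 10⁶.
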
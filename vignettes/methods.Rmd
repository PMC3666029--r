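---
title: "Linked multimodal decomposition: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linked multimodal decomposition: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nwayfusion)
```

## The problem and the model

Studies that acquire several imaging modalities per subject — say a
resting-fMRI amplitude map (ALFF), a diffusion anisotropy map (FA) and a
gray-matter density map (GM) — need a joint decomposition that (a) lets the
strength of the link between modalities vary from component to component,
and (b) still produces spatially crisp, interpretable maps. Fixing the two
requirements with a single tool is hard: cross-correlation methods
(multiset CCA) deliver flexible links but blurry maps; joint ICA delivers
sharp maps but forces one shared subject profile on all modalities.

`nwayfusion` implements the two in sequence. Each modality is a
subjects-by-voxels feature matrix assumed to follow a noisy linear mixture

    X_k = A_k S_k + E_k,     k = 1, ..., n

with spatially sparse, mutually independent source maps `S_k` (rows) and a
subjects-by-components mixing matrix `A_k` whose matching columns are
correlated *across* modalities to a degree that differs per component. The
pipeline is:

1. **Normalization.** Every modality is rescaled by a single factor so its
   mean squared entry equals a common target (1 by default). A single
   multiplier preserves all within-modality structure; it only stops a
   modality with large raw units from dominating the joint steps.
2. **Order selection.** The number of components per modality is estimated
   by the minimum description length criterion on the eigenvalues of the
   subject-space covariance; the joint order is the maximum across
   modalities, because a modest overestimate is benign (see below) while
   discarding a true component is not.
3. **SVD reduction.** `Y_k = X_k E_k` keeps the top-M singular directions
   of the voxel-mean-centered data.
4. **Multiset CCA.** Per-modality transforms `w_k` produce canonical
   variates `D_k = Y_k w_k` maximizing the sum of squared cross-modality
   correlations at matching indices, with unit-variance, mutually
   uncorrelated variates within each modality. Associated maps are the
   least-squares solutions `C_k = pinv(D_k) X_k`.
5. **Joint Infomax ICA.** One unmixing matrix `W` applied to the
   horizontally concatenated maps `[C_1 ... C_n]` maximizes the
   independence of the joint sources `S = W C`.
6. **Back-reconstruction.** `A_k = D_k W^{-1}` gives per-modality subject
   loadings; two loading columns of the same index, one per modality,
   carry the realized inter-modality link.

mCCA aligns the modalities so that the single `W` of joint ICA is a
sensible model for all of them; joint ICA sharpens the maps that mCCA
alone would leave mixed. Component-level inference then works entirely on
`A_k` (group t-tests, inter-modality and clinical correlations) and on
Z-scaled rows of `S_k` (threshold masks).

## Algorithmic choices

**Multiset CCA (SSQCOR, deflationary).** At stage m each `w_k` is updated
in turn, holding the others fixed; the update is the dominant eigenvector
of a generalized eigenproblem, so every cycle increases the objective
monotonically, and the stage stops when the relative objective change
drops below `tol` (1e-10). Stages after the first operate on data with the
earlier variates projected out, which enforces the within-modality
whiteness constraint by construction. Initialization is the deterministic
MAXVAR eigenvector of the stacked correlation matrix, so the CCA stage
needs no seed; ties are broken by forcing the first nonzero entry of each
transform column positive. Within-modality covariances carry a relative
ridge of 1e-8 to tolerate near-collinear reduced data. For n = 2 the
procedure reproduces classical CCA to machine precision (the suite checks
against the closed-form generalized-eigenproblem solution).

**Infomax ICA.** The concatenated maps are sphered by their second-moment
matrix (no mean removal, so `S = W C` holds exactly with the sphering
folded into the returned `W`), then trained with the natural-gradient
update `dW = lr (I + (1 - 2 g(u)) u') W`, logistic `g`, over random
mini-batches of about 1/64 of the voxels. The learning rate (default
0.001) anneals by 0.9 whenever the weights blow up — the last stable
weights are restored — or when the epoch update direction turns by more
than 60 degrees; training stops when the epoch weight change drops below
`tol` (1e-6) or after `max_steps` (512) epochs. The initial weights are
the identity plus seed-controlled noise of scale 1e-3, making every run
bit-reproducible given its seed. Row signs are fixed after fitting so each
joint source's largest-magnitude voxel is positive, and components are
ordered by descending total explained variance (ICA has no intrinsic
order).

The logistic score separates *super-Gaussian* (sparse, heavy-tailed)
sources only. Spatial component maps are sparse in practice, which is why
the classic Infomax nonlinearity is the right default here; sub-Gaussian
sources (e.g. uniform noise fields) are outside its identifiable class and
are not a target of this package. Near-Gaussian recovered sources are
flagged with a warning rather than an error. Separation quality is also a
sample-size question: the finite-sample error of any ICA estimate grows
like sqrt(M/L), so the test suite exercises the Amari-index bound (< 0.1)
at `L >= max(40 M^2, 2000)`, comfortably inside the asymptotic regime; at
a few dozen voxels per weight no estimator meets that bound.

**MDL order selection.** For eigenvalues `l_1 >= ... >= l_p` of the
subject-space covariance (p = subjects) the criterion is

    MDL(m) = -N_eff (p - m) log( geomean(l_{m+1..p}) / mean(l_{m+1..p}) )
             + 0.5 m (2p - m) log(N_eff).

Treating every voxel as an independent sample overstates `N_eff` because
smoothed maps are spatially autocorrelated; by default the effective count
is `L / s` with the stride `s` chosen as the first raster-order lag at
which the voxel autocorrelation falls below 0.1. This stride rule is this
package's own stand-in for a smoothness correction — the literature's
variants differ in detail — and both the corrected and the plain variant
are exposed, with the criterion curve returned for audit. Eigenvalues are
floored at machine-epsilon scale: column-centering makes the smallest one
exactly zero, and the floor contributes an offset that is constant across
candidate orders up to p - 2, so the argmin is unaffected.

**Voxel-wise centering.** Voxel means are removed before the SVD and
stored; covariance-based steps downstream assume zero mean, and the means
are only needed to report reconstructions in original units.

## The synthetic generator

`generate_multimodal()` draws data from exactly the model above. Sources
are sums of 2–6 Gaussian blobs (radius 2–5 grid units, random centers and
signed amplitudes) on a virtual 2-D sheet of about L voxels, centered and
scaled to unit variance. The blob count scales with the field so coverage
stays near 5–20%, which keeps every source super-Gaussian (excess
kurtosis > 0.5 enforced, with bounded redraws) and lets redraws push
within-modality source correlations below 0.1; when redraws cannot, the
small shared part is projected out, which leaves the blob structure
essentially intact. Mixing columns share a latent subject factor,
`A_k[, m] = sqrt(rho_m) z_m + sqrt(1 - rho_m) eps_km`, so matching columns
correlate at `rho_m` in expectation; for cohorts of 100+ subjects the
mixing is redrawn until the realized correlations sit within 0.1 of the
target. Group effects are additive shifts of `d_m` column-sd units on the
first `n_group1` rows of designated columns — the natural analog of
loading t-tests. Gaussian voxel noise (sd 0.2 by default) is added last.

What the generator does *not* emulate: anatomically shaped templates,
physiological noise spectra, registration error, and 3-D smoothing
kernels. Passing recovery tests on this generator shows the algebra and
the estimators work under the model's assumptions, not that any given
real-data decomposition is correct.

**Benchmark conditions.** The documented recovery benchmark uses N = 100
subjects, three modalities of 2000 voxels, M = 5 components with
correlation profile (0.8, 0.6, 0.4, 0.2, 0) and noise sd 0.2. Across 20
seeds the mean matched source correlation is >= 0.90 and the mean mixing
correlation >= 0.85 in at least 95% of seeds. Recovery is scored per
modality: a component with `rho = 0` has *no identifiable cross-modality
pairing* (nothing in the data links its blocks), so demanding one global
permutation across modalities would penalize the method for an
ill-posed question. The residual seed-to-seed spread traces to the shared
unmixing compromise: when the maps `C_k = G_k S_k` carry genuinely
different mixtures `G_k` per modality (the low-rho regime), one `W`
cannot be exact for all of them — re-running with different ICA seeds
reproduces the same score, confirming it is a model limit, not an
optimization failure.

**Overestimation.** With the true order 4 and the same conditions, median
source recovery at M = 5 and M = 6 stays within 0.05 of M = 4, matching
the method's documented tolerance to overestimated orders; the median
mixing recovery peaks at the true order. Per seed the mixing ranking
among nearby orders is within noise, so the suite asserts the median
across seeds rather than a per-seed winner.

## Statistical layer

Group comparisons on loadings use the pooled-variance two-sample t (Welch
available by flag), two-tailed; with 28 + 35 subjects the reference
distribution has 61 degrees of freedom. Correlations (inter-modality and
clinical) are Pearson r with the exact two-tailed transform
`t = r sqrt(N-2) / sqrt(1-r^2)`; at N = 63 this sends r = 0.38 to
p ≈ 0.002 and r = 0.28 to p ≈ 0.025. No multiple-testing correction is
applied by default — the reported p-values are raw, which is also how the
component tables are meant to be read — with Benjamini–Hochberg q-values
available as an option. Z maps divide a source row by its across-voxel
standard deviation without mean subtraction (sources are near zero-mean by
construction) and masks use the strict inequality `|Z| > tau` (3.5 for
feature masks, 2.5 conventionally for reporting tables). Parametric
p-values agree with 10,000-draw permutation oracles within Monte-Carlo
error in the suite.

## Classification protocol

Masked features are *raw* feature values at the union of thresholded
component masks per modality, optionally restricted to the top-k
smallest-p discriminative components. For every non-empty modality
combination (2^n − 1 of them; 7 for three modalities) and each of four
classifiers — linear SVM, RBF SVM, kNN, Gaussian naive Bayes — the
protocol repeats: a stratified random 50/50 split, feature
standardization by the training half's statistics, hyperparameter
selection by 10-fold cross-validation within the training half (C for the
SVMs, gamma for the RBF kernel, k over {1,3,5,7,9}; naive Bayes has
none), training on the full half and scoring on the held-out half; the
mean and maximum accuracy over repetitions are reported. The splits are
stratified because a 63-subject cohort can otherwise produce
single-class training halves, and the same split sequence is reused
across combinations and algorithms so comparisons are paired. When the
masks were derived from the same subjects being classified the report
carries a same-data provenance flag: such accuracies are optimistically
biased and establish feasibility, not generalization.

## Numerical and degenerate-input policy

Volumes with non-finite values inside the mask are rejected, never
imputed (silent imputation corrupts covariance structure). All-zero
modalities, constant score vectors, zero-variance loading columns and
zero-sd component rows raise typed errors naming the offender.
Rank-deficient within-modality covariances are handled by the mCCA ridge;
a singular joint unmixing raises an error carrying the condition number.
Pipeline errors are prefixed with the failing stage. Masks are stored as
raster-ordered coordinate lists (first axis fastest) so written volumes
are bit-reproducible; component maps are written as float32 NIfTI-1.

## Problem sizes in the shipped checks

The bundled tests and the acceptance script run entirely on synthetic
data at desk scale: cohorts of 40–200 subjects, 300–2000 voxels per
modality, 2–8 components, 20-seed repetitions for the stochastic claims,
100–200 split-half repetitions for the classification checks. These sizes
were chosen so every documented property is exercised in minutes on one
CPU; the estimators themselves have no size-specific code paths, and
real-feature matrices (tens of thousands of masked voxels) only change
the constant factors.

## Known limitations

- Components whose mixing correlation is near zero across modalities are
  aligned across modalities only by chance; interpret the joint index of
  such components with care (the `r_profile` is returned so they are easy
  to spot).
- The logistic Infomax stage does not separate sub-Gaussian sources by
  design; extended variants are out of scope.
- The MDL effective-sample stride is a pragmatic smoothness correction,
  not a calibrated estimator of the number of independent voxels.
- Classification on masks derived from the same cohort is circular; use
  the provenance flag and, where possible, an independent cohort.
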
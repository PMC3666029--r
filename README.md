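# nwayfusion

Joint decomposition of multimodal neuroimaging features — linked
multiset-CCA + joint-ICA fusion for two or more co-registered feature
modalities, with component-level group inference and mask-based
classification.

## Who this is for

Imaging groups that collect several feature maps per subject — e.g. a
resting-fMRI amplitude map (ALFF), a DTI fractional-anisotropy map (FA)
and a gray-matter density map (GM) — and want to know which spatial
patterns co-vary across modalities over subjects, which of them
discriminate a patient group, and whether the discriminative regions
predict diagnosis. The package operates on *features* (one 3-D map per
subject per modality, stacked into subjects × voxels matrices), not on raw
4-D time series.

## The model

Each modality k is a noisy linear mixture

```
X_k = A_k S_k + E_k,        k = 1, ..., n
```

with spatially independent source maps `S_k` (components × voxels) and
subject loadings `A_k` (subjects × components) whose matching columns are
correlated across modalities — strongly for some components, weakly or
not at all for others. The pipeline estimates this model in stages:

```
normalize  ->  MDL order selection  ->  SVD:  Y_k = X_k E_k
           ->  multiset CCA:  D_k = Y_k w_k  (max sum of squared
               cross-modality correlations;  D_k' D_k / (N-1) = I)
           ->  associated maps:  C_k = pinv(D_k) X_k
           ->  joint Infomax ICA:  [S_1 ... S_n] = W [C_1 ... C_n]
           ->  back-reconstruction:  A_k = D_k W^{-1}
```

Multiset CCA supplies flexible, per-component inter-modality links; joint
ICA sharpens the maps those links leave mixed. Downstream, two-sample
t-tests on loading columns find group-discriminative components
(modality-common when the same index is significant in ≥ 2 modalities),
Pearson correlations link loadings across modalities and to clinical
scores, and thresholded Z maps (`|Z| > τ`) of discriminative components
define voxel masks whose raw feature values feed four standard
classifiers over all 2ⁿ − 1 modality combinations.

## Worked example

Simulate a 3-modality study with a known ground truth (100 subjects,
2000 voxels per modality, 5 components whose mixing correlates across
modalities at (0.8, 0.6, 0.4, 0.2, 0), a group shift of 1.2 sd on
component 1), fuse it, and inspect recovery:

```r
library(nwayfusion)

g  <- generate_multimodal(N = 100, L_list = c(2000, 2000, 2000), M = 5,
                          rho = c(0.8, 0.6, 0.4, 0.2, 0),
                          d = c(1.2, 0, 0, 0, 0), noise_sd = 0.2, seed = 7)
fr <- fuse(g$mats, fusion_config(M = 5, seed = 7))
fr
#> <fusion_result: mod1 + mod2 + mod3; M = 5, N = 100>
#> variance retained: 99.3%, 99.3%, 99.3%

recovery_report(fr, g$truth)
#> <recovery_report>
#>   modality mean_source_recovery mean_mixing_recovery  amari
#> 1     mod1                0.969                0.966 0.1003
#> 2     mod2                0.957                0.955 0.1032
#> 3     mod3                0.989                0.988 0.0656
```

Matched source and loading correlations near 1 mean the decomposition
recovered the planted components; the Amari index (0 = perfect) measures
residual cross-talk in the loading space. Group inference flags exactly
the planted effect, in all three modalities (a modality-common
component):

```r
stats <- component_stats_table(fr, g$truth$groups)
subset(stats, significant)[, c("modality", "component", "t", "p")]
#>    modality component     t        p
#> 1      mod1         1 -7.32 7.06e-11
#> 6      mod2         1  7.00 3.15e-10
#> 11     mod3         1  7.22 1.15e-10
```

(Signs of t flip with the arbitrary sign of a loading column; the
magnitude is what matters.) Masks from the discriminative component's Z
map (`|Z| > 3.5`) restrict the raw features, and the split-half protocol
scores every modality combination; with this single moderate effect the
RBF-SVM reaches mean accuracies around 0.74–0.81 over 50 repetitions,
e.g.:

```r
fs <- lapply(1:3, function(k)
  build_masked_features(g$mats[[k]],
                        subset(stats, modality == fr$modalities[k]),
                        fr$S[[k]], tau = 3.5))
rep_ <- run_classification(fs, g$truth$groups, n_repetitions = 50, seed = 7)
subset(rep_$summary, algorithm == "RBF-SVM" & combination == "mod1+mod2+mod3")
#>       combination algorithm mean_accuracy max_accuracy n_repetitions
#> 26 mod1+mod2+mod3   RBF-SVM         0.808          0.9            50
```

A command-line front end (`inst/cli/nwayfusion.R`) wraps the same
functions as `simulate`, `fuse` and `classify` subcommands for shell use
(NIfTI volumes in, CSV/JSON and NIfTI component maps out).

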
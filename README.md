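# sdar — subject-dependent artifact removal for motor-imagery EEG

Motor-imagery (MI) brain–computer interfaces suffer from two pervasive EEG
artifacts: ocular (EOG) potentials and volume conduction. The two standard
remedies — ICA-based component rejection and the spherical-spline surface
Laplacian (SL) — help some subjects and hurt others, especially those with
poor MI skills. This package implements **subject-dependent artifact removal
(SD-AR)**: for each subject it evaluates four preprocessing scenarios,

| η | scenario |
|---|----------|
| 0 | raw data |
| 1 | ICA-cleaned (negentropy FastICA, correlation-thresholded EOG rejection, two passes) |
| 2 | surface-Laplacian filtered (spherical splines, o = 10, ρ = 4, λ = 1e−5) |
| 3 | ICA followed by the Laplacian |

estimates a cross-validated classification accuracy for each (functional
connectivity features + LDA), and keeps the argmax:

η\* = argmax_η ACC(η), ties to the smallest η.

Around the selector the package provides the complete pipeline: band-limited
feature extraction in the μ (8–12 Hz) and three β bands (12–15, 15–20,
18–40 Hz) with five pairwise functional-connectivity estimators (Pearson,
motif synchronization, Gaussian-kernel FC, spectral coherence, phase-locking
value); a pooled-covariance LDA with an SVD/shrinkage solver for p ≫ n;
accuracy, Cohen's κ and AUC under stratified k-fold, repeated-split, and
fixed-test validation; k-means partitioning of subjects into three skill
groups; LDA-coefficient relevance maps of connectivity links; and a synthetic
EEG generator (lateralized sensorimotor sources, Gaussian volume-conduction
mixing, biexponential blink artifacts) that gives every stage a testable
ground truth.

## Worked example

```r
library(sdar)

# an artifact-heavy synthetic subject: broad volume conduction + 300 uV blinks
cohort <- generate_cohort(n_heavy = 1, n_clean = 0, seed = 3)
subj   <- cohort[[1]]

fit <- sdar(subj$trials, measure = "pearson", scheme = "kfold10",
            seed = 3, ref_mode = "eog")
print(fit)
```

```
SD-AR fit (measure=pearson, scheme=kfold10, seed=3)
<scenario_score> validation accuracy by scenario:
  eta=0 (raw               )  62.5%
  eta=1 (ica               )  84.4%  <- selected
  eta=2 (laplacian         )  59.4%
  eta=3 (ica_then_laplacian)  78.1%
  test ACC: SD-AR 90.0% | Raw 85.0% | Ind-AR 75.0%
```

The training-portion cross-validation prefers η = 1 (ICA cleaning) for this
blink-contaminated subject — 84.4% against 62.5% on raw data — and the
selected scenario reaches 90.0% on the final 10-fold evaluation, against
85.0% for no preprocessing and 75.0% for forcing both filters (Ind-AR). A
cohort of such fits feeds the skill partition and relevance maps:

```r
raw_acc <- c(s1 = 58, s2 = 62, s3 = 71, s4 = 74, s5 = 86, s6 = 88)
kmeans_skill_groups(raw_acc, seed = 1)
#> <skill_partition> centroids: 87.0 > 72.5 > 60.0
#> GI  GII GIII
#>  2    2    2
```

A thin CLI over the same functions lives at `inst/cli/sdar.R`
(`simulate`, `laplacian`, `ica-clean`, `features`, `classify`, `sdar`,
`group`, `relevance`).

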
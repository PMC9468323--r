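# dfclstm

Classification of brain disorders from resting-state fMRI using the
*dynamics* of functional connectivity between independent brain
networks, with an LSTM sequence classifier.

Most connectivity-based classifiers summarise a scan by one static
correlation matrix. This package implements the alternative hypothesis
end to end: brain networks are recovered by group spatial ICA,
connectivity between them is tracked through a sliding window, and the
resulting *sequence* of network configurations is classified by a
recurrent model, so that effects visible only transiently — or only in
particular connectivity states — still contribute to the decision.

It is aimed at methods researchers in neuroimaging who want a
self-contained, fully testable implementation of this pipeline,
including a ground-truth synthetic cohort generator, so every stage can
be validated without access-restricted clinical data.

## The pipeline

For subject *m* with component time courses `T_m` (T × K), sliding
windows of width 50 TR and step 1 TR produce
`w = floor((T − width)/step) + 1` windowed Pearson matrices

    R_m^w[p, q] = corr(T_m^w[, p], T_m^w[, q]),   R_m^w[p, p] = 1,

whose strict upper triangles (row-major; length K(K−1)/2 — 105 for
K = 15 components, 6670 for the 116-region AAL atlas) are stacked into
the feature sequence `X_m` (d × w). The stages:

1. **Group spatial ICA** — per-subject temporal PCA at 95% retained
   variance (capped at 30), concatenation, second PCA to 20 group
   dimensions, Infomax ICA (natural-gradient, logistic nonlinearity),
   ICASSO-style stability assessment over repeated runs with the
   cluster quality index `Iq = intra − extra similarity`.
2. **Dual-regression back-reconstruction** of subject time courses and
   maps from the group maps (two least-squares stages with intercept).
3. **Dynamic features** as above, plus whole-course static vectors and
   atlas-ROI mean time courses as baselines; detrending and 0.01–0.08 Hz
   zero-phase Butterworth band-pass as post-processing.
4. **Classification** — a single-layer LSTM (30 hidden cells; forget /
   input / output gates, tanh candidate, `C_t = C_{t-1}·f + i·C̃`,
   `h_t = o·tanh(C_t)`) with a two-layer ReLU/softmax head for dynamic
   sequences; linear SVM and random forest for static vectors.
5. **Evaluation** — stratified 10-fold cross-validation with the ICA
   fitted per training fold, and exact confusion-matrix metrics:
   accuracy, sensitivity, specificity, precision, F1, Cohen's kappa,
   macro Jaccard, trapezoidal AUC.

A synthetic cohort generator with known spatial maps, Markov
state-switching inter-component covariance, planted group effects, and
configurable SNR provides ground truth for all of it.

## Worked example

```r
library(dfclstm)

cohort <- make_cohort(n_per_group = c(10, 10), K = 8, n_time = 130,
                      grid_shape = c(10, 10, 6), delta = 0.6, snr = 2, seed = 7)
cohort
#> Synthetic rs-fMRI cohort: 20 subjects, 8 components, 130 time points, 600 voxels
#>  A  B
#> 10 10
#> states: 2  effect pairs: 1-2  delta: 0.6/0.6  snr: 2

red <- two_stage_pca(cohort$voxels, n_group_components = 8)
red
#> Two-stage PCA reduction: 20 subjects, subject dims 30-30 -> group dimension 8

ica <- infomax_ica(red$group_reduced, 8, seed = 1)
ica
#> Infomax ICA: 8 sources, 1875 iterations, converged (final update 9.89e-08)

mean(match_components(ica$sources, cohort$maps)$abs_r)
#> [1] 0.986

sc <- back_reconstruct(ica$sources, cohort$voxels[[1]])
dim(dfc_sequence(sc$timecourses, plan_windows(130, 50, 1)))
#> [1] 28 81

report <- run_experiment(cohort, mode = "dynamic", level = "ica",
                         k = 5, seed = 42, lstm_args = list(n_models = 2))
report
#> Experiment: dynamic features at the ica level, LSTM classifier, 5-fold CV
#>   mean ACC 1.000 +/- 0.000 | SEN 1.000 | SPE 1.000 | F1 1.000 (positive = B)
#>   pooled ACC 1.000 | kappa 1.000 | Jaccard 1.000 | AUC 1.000
```

Reading the numbers: the ICA maps recovered from the noisy voxel data
match the generating maps at mean absolute spatial correlation 0.986;
with K = 8 components each window contributes 8·7/2 = 28 features over
81 windows; and with a strong planted effect (the correlation of one
component pair shifted by 0.6 in one group) the cross-validated
dynamic-ICA-LSTM pipeline separates the groups perfectly — while a
cohort generated with `delta = 0` is classified at chance.

## Command line

```sh
exec/dfclstm simulate --out cohort_dir --seed 1 --delta 0.6
exec/dfclstm run-all  --out results_dir --seed 1
exec/dfclstm decompose --cohort cohort_dir --out decomp_dir --components 15
```

Each subcommand reads and writes the package's archive formats
(4-D NIfTI volumes, TSV label tables, serialised feature archives, JSON
reports) and records a manifest with the configuration hash and seeds.

## Layout

- `R/synthetic-data.R` — ground-truth cohort generator
- `R/pca.R`, `R/infomax.R`, `R/icasso.R`, `R/backrecon.R` — group ICA
- `R/connectivity.R` — windows, correlation features, ROI means
- `R/lstm.R`, `R/baselines.R` — classifiers
- `R/metrics.R`, `R/evaluation.R` — metric suite and CV harness
- `R/io.R`, `R/cli.R`, `exec/dfclstm` — formats, config, command line
- `vignettes/dynamic-connectivity-pipeline.Rmd` — methods notes
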
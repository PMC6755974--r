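# immunotma

Quantifying the bone-marrow immune contexture of adult B-cell acute
lymphoblastic leukemia (B-ALL) from multiplexed immunohistochemistry (mIHC)
tissue-microarray (TMA) images, and relating it to survival.

mIHC stains duplicate 1-mm marrow punches in sequential fluorescent and
chromogenic rounds. Turning those images into clinical statements takes a
chain of steps, each with room for silent error: unmixing chromogens from
RGB brightfield images, registering staining rounds, segmenting cells,
gating them into phenotypes, applying per-spot quality control, comparing
leukemic against healthy marrow, and fitting a penalized survival model on
the resulting features. `immunotma` implements that chain as an R package
whose every stage is validated against synthetic data with known ground
truth — the original study's patient images and tables are not publicly
deposited, so a ground-truthed generator ships as part of the package
rather than as a test afterthought.

The package is aimed at computational pathology and biostatistics readers
who want a tested reference implementation of this class of pipeline, or a
harness for studying its failure modes (cell density, noise, censoring,
cohort size) under controlled conditions.

## The methods in brief

- **Stain separation**: per-pixel optical density `OD = -log10(I / I0)`
  unmixed with the inverse of a row-normalized stain matrix `M`
  (concentrations `c` solve `OD = c M`); the synthetic brightfield forward
  model is the exact Beer–Lambert inverse, `I = I0 · 10^(−t(M) c)`.
- **Registration**: 2-D phase correlation of the two rounds' mean images,
  histogram-adapted to each other and downsized eightfold by block
  averaging; translation only.
- **Segmentation**: Otsu threshold (maximizing between-class variance
  `w0 w1 (mu0 − mu1)^2`) on the smoothed lineage channel; oversized
  components split by a watershed seeded at nuclear intensity maxima; total
  cell count from the binary nuclear area. Spots under 1000 cells fail QC;
  duplicates are averaged per patient.
- **Contexture**: batch mean-centering, two-sided Mann–Whitney U per
  feature with Benjamini–Hochberg control (q < 0.05), log2 ALL-to-control
  median ratios, Spearman-distance/ward.D2 clustering, anchor correlations.
- **Survival**: OS/RFS/EFS endpoints; univariate Cox screen at P < 0.20;
  L1-penalized Cox (`glmnet`) with lambda at minimum cross-validated
  deviance; median split of the linear predictor into high/low risk; Cox
  HR with Wald CI and log-rank p; Schoenfeld PH diagnostics; Gray's test
  with Aalen–Johansen incidence under competing relapse/death; MRD
  negativity at blast fraction < 10⁻⁴; paired-bootstrap AUROC comparison
  (4000 iterations) and IPCW time-dependent ROC at 2/4/6/8 years with
  Harrell's C.

## Worked example

Render one synthetic spot with a planted inter-round shift, recover the
shift, quantify the spot, then fit the risk model on a simulated cohort:

```r
library(immunotma)

spec <- spot_spec(canvas = 512, n_cells = 400, noise_sd = 0.03,
                  shift = c(16, -24), seed = 7)
spot <- generate_tma_spot(spec)
conc <- deconvolve_brightfield(spot$brightfield, spec$stain_matrix)
reg <- register_rounds(spot$fluor, lapply(1:3, function(k) conc[, , k]))
print(reg$registration)
#> Phase-correlation registration: dx = 16.00 px, dy = -24.00 px (peak 0.684, factor 8)

res <- quantify_spot_image(spot$fluor, qc_threshold = 300)
round(as.data.frame(res$quantification)[, -(1:3)], 4)
#>   total_cells qc_pass  CD3_T      B     NK    MAC CD4_T CD8_T CD4_PD1_TIM3
#> 1         412       1 0.1796 0.0777 0.0146 0.0704 0.068 0.051       0.0714
```

The planted shift is recovered exactly; the estimated total (412) is within
3% of the 400 rendered cells, and the proportions match the generated type
mix (e.g. 44 + 5 CD4 T cells of which 5 are PD1+TIM3+, so the true
parent-denominated fraction is 5/49 = 0.102 against 0.0714 measured on this
single 400-cell spot — small-count noise the QC and duplicate averaging
exist to damp).

```r
co <- generate_cohort(cohort_spec(n = 400, censor_rate = 0.2, seed = 7))
ends <- derive_endpoints(co$survival)
X <- as.matrix(co$covariates[, -1])
screen <- univariate_screen(ends$rfs_time, ends$rfs_event, X)
model <- fit_penalized_cox(ends$rfs_time, ends$rfs_event,
                           X[, attr(screen, "retained")], seed = 7)
print(model)
#> L1-penalized Cox risk model (alpha = 1 )
#>   lambda =0.006936 (10-fold CV)
#>   nonzero coefficients:
#>     age                   0.0521
#>     platelet             -0.0056
#>     cd4_pd1_tim3          2.4913
#>     null_feature_2        0.0103
#>   median risk-score cutpoint: 2.047

groups <- risk_stratify(model, X)
print(cox_hr(ends$rfs_time, ends$rfs_event, groups))
#> HR 3.49 (95% CI 2.71-4.49), log-rank p = 1.327e-24

roc <- time_dependent_roc(attr(groups, "lp"), ends$rfs_time, ends$rfs_event)
round(data.frame(years = roc$grid_years, auc = roc$auc), 3)
#>   years   auc
#> 1     2 0.774
#> 2     4 0.796
#> 3     6 0.833
#> 4     8 0.822
```

The screen keeps the three planted signal covariates (age +, platelet −,
CD4+PD1+TIM3+ +) plus one null that slips past P < 0.20; the lasso
coefficients carry the planted signs, and the median split separates the
cohort at HR 3.49.

## Analysis workflow

Numbered drivers under `analysis/` run the full study shape on synthetic
data and write their tables to `results/analysis/` (spot images go to
`scratch/`, which is disposable):

| script | stage |
|---|---|
| `01_simulate.R` | cohort with planted hazards + duplicate TMA spot images |
| `02_preprocess_quantify.R` | deconvolution, registration, segmentation, gating, QC |
| `03_contexture.R` | batch centering, ALL-vs-control tests, ratios, clustering |
| `04_risk_model.R` | screen, penalized Cox, stratification, HR, PH, Gray's test |
| `05_model_comparison.R` | MRD stratification, bootstrap AUROC, IPCW ROC, combined model |

## Package layout

```
R/                  synthgen, imgproc, cellquant, contexture, riskmodel, cli_io
tests/testthat/     unit + property tests with independent oracles
analysis/           numbered workflow drivers
scripts/            acceptance.R
vignettes/          methods vignette (model, assumptions, design choices)
```
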
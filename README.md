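# hematochron

Estimating the age of a hematoma (bruise) from hyperspectral images.

In forensic and clinical practice, hematoma age is usually judged by eye,
which is known to be unreliable. A hyperspectral camera records a full
reflectance spectrum per pixel (here 204 bands across 400–1000 nm), and
that spectrum tracks the biochemical evolution of the lesion: fresh
hematomas are dominated by hemoglobin (Soret absorption near 405–445 nm,
Q-bands at 540/578 nm), bilirubin (≈460 nm) accumulates as heme is
degraded, and all contrast fades as the lesion resolves.

`hematochron` implements a complete, tested pipeline for regressing
hematoma age (in days) from hyperspectral patches:

- **Radiometric normalization** of radiance to relative reflectance,
  `I_ref = (I_raw − I_dark) / (I_white − I_dark)`, with full-cube or
  per-band references, and ENVI cube I/O.
- **Lesion localization and patch extraction**: a deterministic
  spectral-angle + Otsu segmenter (external masks can be supplied
  instead), centroid computation, and exact-size clamped 64×64 patches.
- **Two regressors**: a Lasso baseline on the spatially averaged spectrum
  (glmnet; penalty by subject-grouped internal CV), and a
  spectral–spatial CNN — a per-pixel Conv1D spectral encoder
  (128/64/32 channels, kernels 7/5/3) pooled to a 32-vector per pixel,
  followed by two 3×3 Conv2D blocks (64/128), adaptive 4×4 pooling and a
  2048→256→1 regression head. The network (forward, backprop, Adam,
  BatchNorm, dropout, early stopping on validation MAE) is implemented
  from scratch in RcppArmadillo; no deep-learning framework is required.
- **Leave-one-subject-out (LOSO) evaluation** with MAE, RMSE, R²,
  Acc@±1/2/3 days, and stage-wise errors (early 0–3 d, middle 4–9 d,
  late 10–20 d).
- **Band importance**: SmoothGrad and occlusion sensitivity, combined by
  rank averaging into a consensus from which a Top-20 band subset is
  selected; RGB (460/540/650 nm) and physiological
  (+504/569/578 nm) subsets are built in.
- **A longitudinal phantom simulator** (chromophore kinetics, growing
  then fading lesions, age-dependent spatial heterogeneity, reference
  frames, sensor noise) so the full pipeline runs and is tested without
  any clinical data, which for this problem is not publicly available.

## Worked example

Simulate a small cohort, build patches, and compare the CNN against the
Lasso baseline under LOSO:

```r
library(hematochron)

cohort  <- generate_cohort(phantom_params(n_bands = 60, seed = 11))
dataset <- build_dataset(cohort, masks = "truth")
dataset
#> <cohort_dataset> 96 samples (8 subjects), 60 bands, 48x48 patches, 0 excluded

tc <- train_config(lr = 2.5e-3, lr_schedule = "cosine", batch_size = 4,
                   max_epochs = 18, patience = 8, seed = 11)

lasso <- run_loso(dataset, model_spec("lasso"), tc)
lasso
#> <eval_report> model=lasso, 8 LOSO folds, 96 predictions
#>   pooled:     MAE 3.127 d | RMSE 4.246 d | R2 0.468 | Acc@1d 27.1% | Acc@2d 51.0% | Acc@3d 62.5% (n=96)
#>   mean/folds: MAE 3.127 d | RMSE 4.232 d | R2 0.468 | Acc@1d 27.1% | Acc@2d 51.0% | Acc@3d 62.5% (n=96)
#>   stage MAE:  early 4.08 (n=32) | middle 1.49 (n=32) | late 3.81 (n=32)

cnn <- run_loso(dataset, model_spec("cnn", phantom_cnn_config(60)), tc)
cnn
#> <eval_report> model=cnn, 8 LOSO folds, 96 predictions
#>   pooled:     MAE 1.702 d | RMSE 2.217 d | R2 0.855 | Acc@1d 38.5% | Acc@2d 67.7% | Acc@3d 83.3% (n=96)
#>   mean/folds: MAE 1.702 d | RMSE 2.163 d | R2 0.855 | Acc@1d 38.5% | Acc@2d 67.7% | Acc@3d 83.3% (n=96)
#>   stage MAE:  early 1.66 (n=32) | middle 1.46 (n=32) | late 1.98 (n=32)
```

The spatially blind Lasso baseline reaches a pooled LOSO MAE of 3.1
days; the spectral–spatial CNN reaches 1.7 days. The CNN wins because
part of the phantom's age signal lives in spatial texture that spatial
averaging destroys — the motivation for spectral–spatial modeling. The
stage breakdown shows the mid-course stage (highest spectral contrast)
is easiest and the faded late stage hardest; `cnn$per_day` gives
per-day prediction quartiles.

Band importance and a reduced-band model:

```r
model <- train_cnn(phantom_cnn_config(60),
                   dataset$patches[, , , 1:72], dataset$metadata$age_days[1:72],
                   dataset$patches[, , , 73:96], dataset$metadata$age_days[73:96],
                   tc)
sg   <- smoothgrad_importance(model, dataset$patches[, , , 73:96], seed = 1)
occ  <- occlusion_importance(model, dataset, replacement = "train_mean",
                             band_means = rowMeans(matrix(dataset$patches, 60)))
top  <- top_k(rank_consensus(sg, occ), k = 20, axis = dataset$axis)
top$wavelengths   # concentrates in the Soret / bilirubin / Q-band regions
```

`run_experiment()` chains all of the above (simulation → preprocessing →
LOSO for every configured model and band subset → importance →
comparison tables) from a single declarative config; see
`?run_experiment` and the vignette. A command-line wrapper is installed
at `inst/scripts/run_experiment.R`.

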
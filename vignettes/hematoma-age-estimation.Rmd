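---
title: "Estimating hematoma age from hyperspectral images: models, phantoms, and band selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hematoma age from hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hematochron)
```

## The problem

A hematoma is extravasated blood inside tissue. As it heals, its
chromophore content changes in a fairly stereotyped way: hemoglobin
dominates at first (reddish appearance, strong Soret-band absorption near
405--445 nm and Q-band absorption at 540/578 nm), bilirubin accumulates as
heme is degraded (absorption maximum near 460 nm, yellow-brown
appearance), and finally all optical contrast against surrounding skin
fades as the lesion resolves. Estimating the *age* of a hematoma from its
appearance is a classic forensic problem, and purely visual assessment is
known to be unreliable.

Hyperspectral imaging (HSI) records a full reflectance spectrum per pixel
-- here modeled as 204 bands over 400--1000 nm -- and therefore captures
both the spectral evolution of the chromophore mixture and the spatial
structure of the lesion (growing, then fading and becoming more diffuse
and mottled). `hematochron` implements a complete analysis pipeline for
this regression problem:

1. **Preprocessing**: white/dark reference normalization of radiance to
   relative reflectance, lesion localization, and extraction of
   fixed-size spectral--spatial patches centered on the lesion.
2. **Models**: a spectral-only Lasso baseline on the spatially averaged
   spectrum, and a spectral--spatial convolutional network that sees the
   full patch.
3. **Evaluation**: leave-one-subject-out (LOSO) cross-validation with
   MAE, RMSE, R², threshold accuracies, and a stage-wise error breakdown
   (early 0--3 d, middle 4--9 d, late 10--20 d).
4. **Band importance**: a SmoothGrad + occlusion consensus that selects a
   compact Top-20 band subset for reduced-band acquisition.
5. **A phantom simulator** that generates longitudinal synthetic cohorts
   with the statistical structure the analysis assumes, so the entire
   pipeline is testable without access to any clinical data.

## Radiometric normalization

Raw radiance cubes are converted to relative reflectance with white and
dark reference measurements,

$$ I_\mathrm{ref} = \frac{I_\mathrm{raw} - I_\mathrm{dark}}
                         {I_\mathrm{white} - I_\mathrm{dark}}, $$

element-wise per band and pixel. Values are kept at full floating
precision and are deliberately **not clipped** to $[0,1]$: sensor noise
legitimately pushes reflectance slightly outside the unit interval and
clipping would discard information. References may be full cubes or
per-band spectra (both occur in practice, e.g. in-scene white tiles). A
zero denominator anywhere it is used raises an error naming the band and
pixel rather than silently propagating `Inf`.

## Lesion localization

The pipeline only needs the lesion *center* to place a patch. Interactive
foundation-model segmentation is out of scope here (it is an external RGB
tool with downloadable weights); instead the package ships a
deterministic spectral-contrast segmenter and accepts externally supplied
masks wherever a mask is consumed, so outputs of any external segmenter
can be injected.

The built-in segmenter scores every pixel by its spectral angle to a
reference "healthy skin" spectrum (the median spectrum of the prompt-box
border, or of the image border if no box is given), thresholds the score
map with Otsu's method, and keeps the largest connected component.
Samples whose peak contrast falls below a configurable floor (default
0.025 rad) are treated as having no visible hematoma and are excluded
with a logged reason -- the same policy a human operator applies to
acquisitions taken before the hematoma forms or after it has resolved.

Patches are extracted as exact `64 x 64` windows (configurable) centered
on the rounded mask centroid, with **clamping** at image borders: the
window is shifted inside the image so every patch contains only real
pixels, never padding. Coordinates are 1-based `(row, col)` with closed
windows, matching R indexing.

## The two regressors

**Lasso baseline.** All pixel spectra of a patch are averaged into one
per-band mean vector; an L1-penalized linear model then regresses age on
this spectrum. The penalty is chosen by internal cross-validation over a
logarithmic grid, grouped by subject so the internal folds never split a
subject. The L1 penalty zeroes uninformative bands, giving an implicit
wavelength selection. By construction this model cannot use any spatial
information -- that is the point of the comparison.

**Spectral--spatial CNN.** The network has two stages. A *spectral
encoder* applies a stack of three 1-D convolutions along the band axis
independently to every pixel spectrum (weights shared across pixels;
implemented by folding pixels into the batch dimension, which is
mathematically identical): channel widths 128/64/32 with kernels 7/5/3
and same-padding, each convolution followed by ReLU and then BatchNorm.
The encoder output is adaptively average-pooled to length 16 and then
averaged across the 16 positions, yielding one 32-vector per pixel. We
read the architecture's consecutive "pool to 16, then spectral
average" stages literally and apply them sequentially; since both steps are
linear this is equivalent to a single weighted band average, and a config
flag (`spec_pool_len`) exposes the pooled length in case a different
reading was intended. The per-pixel embeddings form a `32 x 64 x 64` map
processed by a *spatial stage*: two 3x3 convolutions (64 then 128
channels, ReLU + BatchNorm, each followed by 2x2 max pooling), adaptive
4x4 average pooling, and a `2048 -> 256 -> 1` regression head with
dropout 0.3. BatchNorm is placed *after* the activation (conv -> ReLU ->
BN), following the architecture note, although conv -> BN -> ReLU is the
more common order.

No deep-learning framework is available in the target environment, so
the network -- forward pass, backpropagation (including through batch
statistics), Adam, dropout, and early stopping -- is implemented directly
in RcppArmadillo in single precision. Convolutions are expressed as
contiguous-block GEMMs (band-shifted column blocks for the spectral
stage, im2col for the spatial stage). The backward pass is verified
against central finite differences in the test suite, and the full-scale
shape trace is asserted layer by layer.

**Training protocol.** Adam with learning rate $10^{-3}$, batch size 32,
weight decay $10^{-5}$; random horizontal and vertical flips (independent
probability 0.5 per axis) as augmentation; up to 100 epochs with early
stopping when validation MAE fails to improve by at least 0.01 days for
25 consecutive epochs, restoring the best-epoch weights. The training
loss is mean squared error -- the conventional regression default, chosen
because RMSE is reported alongside the MAE that early stopping monitors.
All of these are `train_config()` fields.

## Leave-one-subject-out evaluation

All partitioning is by subject: each LOSO fold holds out every sample of
one subject and trains on the rest, so no subject's longitudinal series
is ever split across train and test. Within each fold, early stopping
needs validation data; we hold out two *training* subjects (seeded per
fold), preserving subject-level leakage prevention inside folds. Folds
are ordered by sorted subject id, so the fold structure is deterministic.

Reports contain per-fold metrics, their unweighted mean (the convention
used for headline numbers), pooled-over-all-predictions metrics (the two
differ when fold sizes differ; both are emitted), per-stage MAE, and
per-day prediction quartiles. Pooled R² is the primary R² (per-fold R²
on a dozen samples is unstable). A constant truth vector makes R²
undefined (`SS_tot = 0`); it is flagged `NA` rather than forced to a
number. Predictions are continuous and are not rounded to whole days
before computing metrics.

## Band importance and reduced-band acquisition

Four input configurations reuse the same architecture, differing only in
`n_bands`: **rgb** (bands nearest 460/540/650 nm -- Bayer-filter peak
sensitivities, emulating a color camera), **physio** (rgb plus
504/569/578 nm, targeting heme-degradation chromophores), **full** (all
bands), and **top-20** (data-driven).

Top-20 selection combines two attribution methods computed on one
tuning-split model (a single model, not per fold; per-fold attribution
remains possible by calling the functions per fold):

- **SmoothGrad**: mean absolute input gradient over noise-perturbed
  copies of the input, aggregated per band. Defaults: noise sd = 10% of
  the input sd, 25 draws -- the method's customary settings, since no
  parameters are prescribed for this application.
- **Occlusion**: replace one band in every sample by its training-set
  mean (replacing by an in-distribution value removes *information*
  without leaving the data manifold; zero-replacement is available as a
  policy flag) and record the MAE degradation. Scores are signed.

Within each method, bands are ranked (1 = most important, ties get
average ranks); the consensus is the mean of the two ranks, lower =
better, and the Top-k are the k bands with the smallest consensus rank,
ties at the cut broken toward the lower band index. Attribution inputs
are the tuning-split validation samples; the occlusion replacement means
come from the training split.

## The phantom simulator

No public dataset exists for this problem, so the package generates
longitudinal phantoms whose structure matches the study design the
analysis assumes: a cohort of subjects imaged repeatedly over three
weeks (daily at first, then at roughly 48-hour intervals), full VIS--NIR
sampling, and lesions that grow to a mid-course maximum and then fade.

**Spectra.** Chromophore absorption curves are sums of Gaussian peaks
with the documented maxima (oxyhemoglobin 415/540/578 nm, deoxyhemoglobin
430/555 nm, bilirubin 460 nm; FWHM 20 nm for the Soret peaks, 25 nm for
Q-band and bilirubin peaks) plus a melanin background that decreases
monotonically with wavelength. These are deliberately *parametric
approximations*, not tabulated extinction coefficients: only peak
positions are prescribed, and a parametric form keeps the generator
dependency-free and its informative bands controllable. A band is
recorded as "informative" when any age-varying chromophore absorbs more
than 0.15 of its own maximum there -- these are the bands a faithful
attribution method should recover.

**Kinetics.** Total hemoglobin decays exponentially (e-folding 6 days)
from its day-0 maximum; the oxygenated fraction relaxes from 0.75 to
0.40; bilirubin rises from exactly zero at day 0 to a peak at day 7 and
declines; and a contrast-fade factor $\exp(-(t/22)^4)$ drives every
lesion weight to zero as the lesion resolves. Middle ages therefore show
the highest spectral contrast, and the late stage fades -- the stage
structure the evaluation expects.

**Space.** The lesion has a super-Gaussian radial profile
$\exp(-(r/R)^4)$ (sharp core, smooth shoulder) whose radius grows from 4
px to a day-6 maximum of 14 px and shrinks thereafter. Optical depth is
modulated by a smooth random heterogeneity field whose *relative
amplitude increases with age*, $a(t) = a_0\, t/(t+4)$ with default
$a_0 = 0.6$: young hematomas are smooth, old ones mottled. This is the
deliberate design split of the age signal: part lives in the mean
spectrum (available to both models) and part in spatial texture, which
spatial averaging destroys -- so the Lasso-vs-CNN comparison is
reproducible *in kind* on phantoms. Setting `heterogeneity = 0` removes
the spatial channel entirely.

**Rendering.** Lesion reflectance follows a Beer--Lambert mixing model,
`skin * exp(-depth * profile * (1 + a(t) h(x,y)) * sum_c w_c(t) mu_c(lambda))`,
with a per-subject skin baseline (melanin level, lesion depth factor,
lesion position, radius scale, and time-course rate jitter drawn per
subject). White references are flat and bright with a mild spectral tilt
and a 2% horizontal illumination gradient; dark references are flat and
low. Gaussian noise (multiplicative sd 0.01, additive sd 0.002) is
applied to the *radiance* only, so reference-based normalization recovers
reflectance up to that noise. Each subject is driven by its own random
stream derived from the master seed, so enlarging a cohort never perturbs
existing subjects' data.

**What the phantom does not model.** Radiative transfer in layered skin,
depth-resolved lesion structure, camera PSF and stray light, shot-noise
statistics, inter-day illumination drift, and real inter-subject
biological diversity. Phantom results therefore demonstrate that the
pipeline's machinery is correct and that its comparisons point in the
expected direction under controlled conditions; they say nothing
quantitative about clinical accuracy, and error rates measured on real
clinical cohorts cannot be reproduced from synthetic data.

## Problem sizes and numerical choices

The packaged experiments run on a deliberately scaled-down cohort: **8
subjects x 12 ages (0--19 d), 48 x 48-pixel frames, 60 bands**, with a
reduced-width CNN (`phantom_cnn_config()`: spectral channels 4/4/8,
spatial 8/16, 32-unit head, spectral pool length 8) trained for up to 18
epochs with batch size 4, patience 8, and cosine learning-rate annealing
from 2.5e-3 down to 1.25e-4. These sizes were chosen so a full
three-seed LOSO comparison runs on one desktop CPU core in minutes while
leaving the task non-trivial: the slim CNN still beats the Lasso
baseline only by exploiting the spatial texture channel. The small batch
gives the optimizer enough updates per epoch on a 60-sample training
fold, and the annealed schedule reaches a converged model within the
short epoch budget; the full-scale protocol (`train_config()` defaults:
constant learning rate 1e-3, batch 32, 100 epochs, patience 25) remains
the default for full-size data. The full-scale architecture
(`cnn_config()`) is exercised structurally (shape trace, gradient
checks) rather than trained in tests.

Band attribution is computed once per study on a tuning-split model and
evaluated on the tuning-split validation samples (the attribution data
split is a free choice; held-out samples avoid attributing to memorized
noise). The occlusion replacement means come from the training split.

Other numerical choices: single-precision arithmetic throughout the
network (BatchNorm statistics accumulate in double); BatchNorm epsilon
1e-5 and momentum 0.2 (faster running-stat settling on small datasets,
where evaluation-mode predictions otherwise lag training by several
epochs); He initialization, with the output bias initialized to the
training-mean age so the head starts at the optimal constant predictor;
inputs standardized to zero mean and unit variance with training-set
statistics (stored in the model and applied at prediction time, with the
chain rule applied to input gradients); Adam (0.9, 0.999, 1e-8) with L2
weight decay added to gradients and the global gradient norm clipped at
25 to tame occasional loss spikes on small batches; adaptive pooling
windows use the floor/ceil convention, so band counts that do not divide
the pooled length are handled (and output lengths larger than the input
duplicate windows, which makes 3-band RGB inputs legal). Ties in
`nearest_band()` and in Top-k cuts break toward the lower band index;
mask centroids round half up.

## Limitations

- The CNN is CPU-only and single-threaded by design of the environment;
  full-scale training (204 bands, 64 x 64 patches, hundreds of samples)
  is possible but slow, on the order of GPU-minutes-equals-CPU-hours.
- The built-in segmenter assumes the lesion is the dominant
  spectral-contrast object in the prompt region; it is a stand-in for
  interactive segmentation, not a clinical tool.
- Phantom realism is limited as described above; in particular the
  phantom's noise and inter-subject variation are stipulated, not fitted
  to any measured data.
- `run_experiment()` reports both mean-over-folds and pooled metrics;
  when comparing to external numbers, check which convention they use.
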
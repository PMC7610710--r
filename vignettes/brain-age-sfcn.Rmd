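---
title: "Brain-age prediction with a lightweight fully convolutional network"
author: "sfcn package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age prediction with a lightweight fully convolutional network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfcn)
```

## The problem and the model

Brain age is the age a model predicts for a person from their brain image
alone; the *brain-age delta* — predicted minus chronological age — is a
candidate biomarker of accelerated or decelerated ageing. This package
implements a complete brain-age pipeline around the Simple Fully
Convolutional Network (SFCN), a deliberately small 3D CNN for
single-channel volumetric MRI registered to a standard space.

The SFCN has seven blocks. Blocks 1–5 each apply a 3×3×3 convolution
(stride 1, padding 1, so shape is changed only by pooling), a normalization
layer with learnable affine terms, 2×2×2 max pooling (stride 2, odd
dimensions floor-divide) and a ReLU. Block 6 is a 1×1×1 convolutional
bottleneck with normalization and ReLU. Block 7 pools the entire remaining
spatial grid to 1×1×1 per channel (an adaptive average pool — this is what
makes the network fully convolutional and tolerant of input size), applies
dropout (training only, rate 0.5), maps to the output bins with a 1×1×1
convolution, and finishes with a softmax. With channel widths
`[32, 64, 128, 256, 256, 64, 40]` and a 160×192×160 input, the block-5
feature map is 5×6×5 and the model has 2,952,936 trainable parameters —
about 3.0 million, less than a tenth of a 3D ResNet-18 (33.2 million; the
3D ResNet-50 has 46.2 million). The ResNet builders exist as comparison
models and to make those counts checkable:

```{r, eval = FALSE}
count_parameters(build_sfcn(sfcn_spec()))          # 2952936
count_parameters(build_resnet3d(resnet3d_spec(18)))  # 33180520
sfcn_shape_trace(sfcn_spec())[5, ]                 # 5 6 5
```

The final 1×1×1 convolution is mathematically a linear layer on the pooled
64-channel vector; it is implemented as a convolution so the parameter
tally (64·40 weights + 40 biases) is unambiguous. In the 3D residual
networks, convolutions followed by a normalization layer carry no bias,
shortcuts that change resolution or width are 1×1×1 strided convolutions
with normalization, and the stem is a 7×7×7 stride-2 convolution: this
dialect reproduces the printed 33.2M/46.2M counts exactly, which is how the
two open choices (stem kernel, shortcut style) were pinned down.

## Soft classification instead of regression

Rather than regressing age directly, the age axis is discretized into bins
(`age_bins()`): 40 one-year bins between 42 and 82, or 40 two-year bins
between 14 and 94. The training target for a subject of age $y$ is a
Gaussian evaluated at the bin centers and renormalized,
$t_c \propto \exp(-(\mathrm{age}_c - y)^2 / 2\sigma^2)$, with $\sigma = 1$
year on one-year bins. Density evaluation at centers (rather than
integration over bins) keeps the code simple; the difference is
$O(\text{bin width}^2)$ and negligible at these widths. The loss is the
Kullback–Leibler divergence $\mathrm{KL}(t \,\|\, x) = \sum_c t_c \log(t_c
/ x_c)$ — the direction that reduces to ordinary cross-entropy when the
target is one-hot, which is also how the two-class sex variant is trained.
Predicted age is decoded as the expectation
$\hat{y} = \sum_c x_c \cdot \mathrm{age}_c$, so it always lies inside the
bin range. Where a width other than one year is used and no width is
stated, the label $\sigma$ defaults to the bin width (a configurable
assumption).

## Training recipe and augmentation

`sfcn_train()` implements the reference recipe: SGD with initial learning
rate 0.01 multiplied by 0.3 every 30 epochs, L2 weight decay 0.001, batch
size 8. Momentum is not specified by the recipe; 0.9, its standard
companion, is the default and can be set to 0. Adam is retained as a
comparison option. During training only, each volume is (1) shifted by an
integer offset drawn uniformly from −2…+2 voxels independently per axis
(the shift magnitude "0, 1 or 2" is made direction-symmetric so the brain
is not systematically displaced; vacated voxels are zero, the background
value after brain extraction), and (2) mirrored about the sagittal plane
with probability 0.5 — the left-right axis is axis 1 by the loader's
canonical orientation. Validation and test forward passes are never
augmented, and dropout and batch statistics are frozen at inference, so
repeated inference passes are identical. After every epoch the validation
metric is computed and the parameters of the best validation epoch (lowest
MAE; ties to the earliest epoch) are restored into the returned fit.
Training is deterministic given the seed and a fixed machine; epochs are
numbered from 1, so `lr_at_epoch(cfg, 1)` is the initial rate.

The engine behind the layers (3D convolution via im2col and BLAS
multiplication, max pooling with argmax bookkeeping, batch/instance
normalization, backpropagation, SGD/Adam) is part of this package and is
verified against central finite differences in the test suite; batch
normalization uses biased batch variance for normalization and running
statistics, and weight decay applies to all parameters including
normalization affines. Weights are He-initialized (normal with SD
$\sqrt{2/\mathrm{fan_{in}}}$); the build seed is recorded so
initialization is reproducible.

## Bias correction

Brain-age predictions regress toward the cohort mean (regression dilution,
plus non-Gaussian label distributions), leaving the delta negatively
correlated with age. `fit_bias()` fits $x = a y + b$ by ordinary least
squares on a labeled validation set; `apply_correction()` inverts it,
$\hat{x} = (x - b)/a$, which needs no labels and therefore transfers to an
unlabeled test set under the assumption that $a$ and $b$ generalize. The
API is deliberately two-step — fit on one set, apply to another — and never
refits silently. On the fitting set, OLS orthogonality makes the corrected
delta exactly uncorrelated with age; the correction is strictly monotone,
so subject ranking is preserved, and any MAE increase it causes is the
price of the affine re-scaling and should be reported alongside. The
correction is linear by design; a polynomial extension is intentionally out
of scope (the `bias_model` stores a degree-1 fit only).

## Ensembling

`ensemble_mean()` averages predicted ages across models — the simplest
combination rule. Its value comes from decorrelation: for every model pair,
`pairwise_improvement()` computes the MAE gain of the two-model average
over the pair's mean single-model MAE, next to the Pearson correlation of
the pair's delta vectors (`delta_correlation_matrix()`). Averaging can
never hurt in the aggregate — by the triangle inequality the ensemble MAE
is at most the mean of member MAEs on any dataset — and helps most when
deltas are least correlated. In this package the "modalities" of a
semi-multimodal ensemble are realized as deterministic pseudo-modalities of
the phantom volumes (`derive_modalities()`: raw, smoothed, edge,
tissue-mask channels), a documented surrogate for the distinct
preprocessing pipelines (linear/nonlinear registration, grey/white-matter
segmentations) applied to real T1 images.

## Synthetic phantoms: what they do and do not show

Real cohorts are access-restricted, so `generate_cohort()` renders small
concentric-ellipsoid "brains" with a planted, monotone, deterministic age
signal plus Gaussian intensity noise: the dark central "ventricle" radius
grows by 0.1 voxels/year, the bright cortical rim thins by 0.05
voxels/year (gross atrophy-like geometry), and sex scales the whole head by
±5%. Ages are uniform over 42–82 by default (a `skewed` mode exercises the
non-Gaussian-label motivation for bias correction). The default grid is
32×64×32 — divisible by $2^5$, so the unmodified five-pool architecture
runs; full-size 160×192×160 generation is supported but not default. The
tissue intensities are 0.1/0.5/1.0 on a zero background with noise SD 0.05,
chosen so the morphological signal dominates but single-voxel intensities
are unreliable.

Passing tests on phantoms demonstrate that the architecture, loss,
augmentation, optimizer, selection, ensembling and correction machinery are
wired correctly and can extract a known morphological age signal. They say
nothing about MRI texture, scanner effects, registration error or real
anatomical variation, and the headline accuracies reported for real
cohorts (e.g. MAE near 2 years) are not reproducible at this scale: they
require restricted data and GPU-weeks of training. The desk-scale
experiment in the test suite trains a reduced-width SFCN
(`[4, 8, 16, 16, 32, 16, 40]`, about 27k parameters) on a 200-subject
phantom cohort (140/30/30 split) for 25 epochs — sized so the whole run
takes minutes on one CPU — and checks it beats the constant-mean-age
predictor (whose MAE is about 10 years for uniform ages on a 40-year
range); the sex variant trains 10 epochs and is checked against 90%
accuracy. With the step schedule unchanged, these short runs use the
initial learning rate throughout, matching the recipe's first decay at
epoch 31.

## Numerical choices and degenerate inputs

* Output probabilities are produced by a max-shifted softmax; the KL loss
  clamps probabilities at $10^{-12}$ before logs.
* `make_bins` requires the range to be an exact bin-width multiple; ages
  outside the range warn (mass piles at the boundary) rather than fail.
* A bias slope smaller than $10^{-6}$ in magnitude is rejected: the
  correction would not be invertible. Degenerate variances (constant
  predictions or ages) are errors in the correlation metrics, not NaNs.
* Bootstrap uncertainty resamples subjects (rows), never residuals, with a
  local seeded RNG that leaves the session RNG untouched.
* Spearman ties get average ranks (the `stats::cor` convention).
* Center crop/pad: symmetric with the extra voxel at the high-index end for
  odd remainders, so 182×218×182 maps onto 160×192×160 reproducibly.
* Best-epoch ties resolve to the earliest epoch; the restored model also
  restores the normalization running statistics from that epoch.

## Known limitations

The engine is CPU-only and single-threaded beyond BLAS; full-size
160×192×160 training is out of reach here (the builders and forward pass
support it, and parameter counting is exact at full size). Gradient
determinism is promised per machine and seed, not across BLAS
implementations. Instance normalization with a 1×1×1 feature grid (as in
the bottleneck block of very small inputs) degenerates to its offset
parameter — with tiny inputs, prefer batch normalization. The phantom
generator plants a single dominant monotone signal; it cannot probe
overfitting regimes that need realistic anatomical variability.
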
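---
title: "Activation sparsity as a processing-based predictor of beauty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activation sparsity as a processing-based predictor of beauty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsebeauty)
```

## The model

The fluency account of aesthetics holds that beauty judgments track how
efficiently the perceiver's visual system processes a stimulus, not just
what the stimulus contains. `sparsebeauty` operationalizes that idea with
a deep convolutional encoder standing in for the visual hierarchy: every
image is pushed through the network, the post-ReLU activations of each
measured layer are flattened into one vector per layer, and the
*sparsity* of each vector — how unequally activity is distributed over
units — is taken as the layer's processing-efficiency statistic. A sparse
code (few strongly active units, most near silence) is an efficient one.

Sparsity is measured by the Gini index of the activation vector
$x_1 \le x_2 \le \dots \le x_n$ (sorted ascending, $i$ one-based):

$$G = \frac{\sum_{i=1}^{n} (2i - n - 1)\, x_i}{n \sum_{i=1}^{n} x_i},$$

equivalently the normalized mean absolute pairwise difference
$\sum_{i,j} |x_i - x_j| / (2 n^2 \bar x)$. $G$ is 0 for a perfectly
uniform code and $(n-1)/n$ for a one-hot code. Among common sparsity
statistics, the Gini index satisfies the full set of inequity axioms —
scale invariance, permutation invariance, the Robin-Hood transfer
principle, cloning invariance, and sensitivity to appended zeros
(kurtosis and the $L_1$ norm each fail at least one); the test suite
asserts each axiom directly, and an independent pairwise-difference
implementation (`gini_pairwise_oracle()`, an explicit double loop that
shares no code with the sorted formula) guards the primary path. The
Treves–Rolls sparseness $S = 1 - (\bar x)^2 / \overline{x^2}$ is
provided as the common neuroscience alternative; we report the plain
$1 - a$ form without small-$n$ normalization and record the metric name
in every output table so the convention is auditable.

Ratings enter the pipeline as per-image mean opinion scores on a
declared instrument scale and are mapped affinely onto a common
$[0, 5]$ scale using the *instrument* bounds, not the empirical
min/max — empirical bounds would make the rescaled scores depend on the
sample rather than the rating instrument.

## The regression battery

With an $n \times 15$ sparsity profile (one column per measured layer)
and optionally PCA-reduced activation features, five model families
quantify how much rating variance each representation explains:

1. **Per-layer univariate** — one OLS model per layer on that layer's
   (z-scored) sparsity; the battery row reports the mean $R^2$ over
   layers.
2. **All-layer sparsity ridge** — one L2-penalized model on all 15
   sparsity columns.
3. **Per-layer PC ridge** — one ridge model per layer on the principal
   components retaining 80% of that layer's activation variance.
4. **Global PC ridge** — the first three PCs of every layer
   (45 predictors at full depth).
5. **Combined** — the 45 PC columns plus the 15 sparsity columns
   (60 predictors).

All models are scored by $k$-fold cross-validation (default 10 folds)
repeated $R$ times (default 100): per test fold the coefficient of
determination is computed between held-out truth and prediction as
$1 - \mathrm{SSE}/\mathrm{SST}$ with SST centered on the *test-fold*
mean, then averaged over folds, then over repeats. Negative values are
retained — a model genuinely can predict worse than the test-fold mean,
and clipping would bias null calibrations. For multivariate families an
adjusted value $1 - (1 - R^2)(n-1)/(n-p-1)$ is also reported, applied
to the CV-averaged $R^2$ with $n$ the total sample size and $p$ the
predictor count; since there is no canonical adjustment under repeated
CV, the formula travels with the run metadata.

### Ridge penalty

The penalty $\lambda$ is selected from a grid of 50 log-spaced values
in $[10^{-4}, 10^{4}]$ (predictors are z-scored, so one grid serves all
designs). By default selection is *nested*: an inner 5-fold CV on each
outer training fold picks that fold's $\lambda$, so the held-out fold
never influences the penalty; a `"global"` mode (one $\lambda$ from a
full-data CV) is available for comparison. Ties in the inner-CV MSE
break toward the larger, more conservative penalty. Reported
coefficients always come from a full-data fit at the full-data
CV-selected $\lambda$, because fold-wise coefficient vectors are not
uniquely defined. Fits go through glmnet with standardization disabled
(the pipeline owns its z-scoring) and a tightened convergence threshold
so that the vanishing-penalty limit reproduces OLS to 4 decimals.

### Significance

The CV-averaged $R^2$ has no standard parametric null, so p-values come
from a seeded permutation test: the response is permuted $B$ times
(default 10,000; analyses at desk scale use 99–199) and
$p = (1 + \#\{R^2_{\mathrm{perm}} \ge R^2_{\mathrm{obs}}\})/(1 + B)$.
Two cost-control choices are deliberate and documented here: within the
null, CV runs a single repetition, and for ridge families $\lambda$ is
frozen at the observed full-data CV-selected value rather than re-tuned
per permutation. Calibration is checked empirically: over 200 replicate
null datasets the test at $\alpha = 0.05$ rejects at a rate inside the
binomial band around the nominal level.

### Preprocessing leakage

Replicating the analysis convention this package implements, the PCA
(one per layer per dataset) and the z-transform are fit on the *full*
dataset before cross-validation. That leaks test information into
preprocessing. Because the difference is itself scientifically
interesting, both modes are exposed:
`run_model_battery(..., preprocess = "full_data")` (default) replicates
the convention, while `preprocess = "fold_wise"` refits the z-scoring
and the PCA inside every training fold and projects the held-out fold —
a leakage-free evaluation. Per-layer univariate fits are identical under
both modes (OLS predictions are invariant to affine rescaling of the
predictor), which the test suite asserts; differences appear only in the
penalized multivariate families. The fold-wise mode reports no
permutation p-values (its null would require refitting every fold-wise
PCA per permutation) and reuses the full-data coefficients.

## Encoder backends

The measurement plan of the full-scale analysis is the VGG16
architecture at $224 \times 224$ input: 13 convolution layers
(`conv1_1` … `conv5_3`; feature maps $H \times W \times C$ from
$224 \times 224 \times 64$, i.e. 3,211,264 activations, down to
$14 \times 14 \times 512$) and two 4096-unit fully connected layers.
Activations are measured after ReLU and before the block's max-pooling
step; pooling layers themselves are not measured. Pretrained weights
are supplied by the user from a local `.rds` file and are never fetched
implicitly — without weights the backend still exposes the complete
layer-shape plan, which is all the structural checks need.

For self-contained work the package ships a *fixture* backend: a small
seeded network (32×32×3 input; 3×3 convolutions of 16, 32 and 64
channels, each followed by 2×2 max pooling; one 64-unit FC layer) with
He-scaled Gaussian weights and zero biases drawn deterministically from
a seed. Inference uses the package's own forward pass (im2col
convolution, max pooling, ReLU), is dropout-free and bit-reproducible,
and the test suite cross-checks the convolution against a brute-force
quintuple-loop oracle.

Preprocessing decodes PNG/JPEG, replicates a grayscale channel to RGB
and drops alpha (each with a warning), resizes to the backend's input
size by bilinear interpolation *without* preserving aspect ratio (the
resampling method is recorded in run metadata; source datasets in this
field vary wildly in geometry and the non-aspect-preserving resize is
the assumption least dependent on per-dataset cropping policy), and
applies the backend's normalization: ImageNet per-channel mean/SD for
the VGG16 adapter, identity ($[0,1]$) for the fixture network.

## The synthetic generator

The generator produces data with the statistical structure the analysis
assumes, plus known ground truth, so parameter recovery is measurable:

* **Activations.** For image $i$, layer $l$: iid draws from
  $\mathrm{Gamma}(k_{il}, 1)$. The Gamma family is chosen because its
  population Gini has the closed form
  $\Gamma(k + \tfrac12) / (\Gamma(k+1)\sqrt{\pi})$ — 0.5 at $k = 1$,
  $1/3$ for the uniform limit — giving analytic anchors that do not
  trust the code under test. Shapes are mixed per image as
  $k_{il} = k_{\min} + (k_{\max} - k_{\min})(\rho u_i + (1-\rho) v_{il})$
  with a shared per-image latent $u_i$, so layer sparsities of one image
  correlate (weight $\rho = 0.5$ by default, producing cross-layer
  sparsity correlations around 0.4–0.5, the regime a real encoder
  exhibits). Default shape range $[0.5, 5]$ spans population Ginis of
  roughly 0.62 down to 0.23.
* **Scores.** $y^* = S\beta + \varepsilon$ on the z-scored sparsity
  matrix, $\varepsilon \sim N(0, \sigma^2)$; either $\sigma$ is given or
  a target population $R^2$ sets it through
  $\sigma = \sqrt{\mathrm{Var}(S\beta)(1 - R^2)/R^2}$. $y^*$ is mapped
  *affinely* onto $[0,5]$ (clipping would distort the linear generative
  model; $R^2$ is invariant to the affine map, so recovery targets are
  unaffected). Default $\beta$ alternates sign with magnitudes spread
  over $[0.5, 1.5]$ score units per SD of sparsity: every layer
  matters, signs are mixed as in the real per-layer coefficient
  profiles, and at the reference scale ($n = 2000$, 15 layers of 256
  activations) the design has the power to recover all 15 coefficient
  signs and the coefficient profile at correlation above 0.9.
* **Images.** Two 32×32 PNG classes drive the encoder end to end:
  `sparse_dots` (a few bright Gaussian blobs on black) and
  `dense_noise` (full-field uniform noise). Under the fixture network
  with zero biases, blob images activate few spatial positions and
  yield much sparser early-layer codes (median conv1 Gini ≈ 0.97
  vs ≈ 0.7), so class-dependent scores are recoverable from layer-1
  sparsity alone.

What the generator does *not* emulate: natural-image statistics,
ImageNet-tuned filters, rater disagreement, or any nonlinear
sparsity–beauty relationship. Passing recovery tests therefore shows the
statistical machinery is correct and calibrated — not that sparsity
predicts beauty in any particular real dataset; that question needs the
external image sets and pretrained weights the full-scale mode accepts.

## Numerical choices and degenerate inputs

* All-zero activation vectors raise an error rather than returning 0 or
  NaN — a layer that never fires has no defined code inequity, and a
  silent sentinel would propagate into the regressions. Negative
  entries and vectors shorter than 2 are likewise rejected.
* Ties in the Gini sort need no tie-break: the sum is invariant to the
  order of equal values (covered by a property test). Sums accumulate
  in extended precision, safe for the 3.2-million-entry first
  convolution layer.
* The retained-component rule takes the smallest $k$ whose cumulative
  explained-variance fraction reaches the target *minus* $10^{-8}$: an
  exact-boundary spectrum such as $(0.5, 0.3, 0.2)$ at target 0.8 must
  retain 2 components, which strict binary-float comparison would break.
* PC signs are fixed by forcing each component's largest-magnitude
  loading positive; z-scores use the sample-SD ($n-1$) convention,
  which changes values at small $n$.
* Zero-variance predictor columns, constant activation matrices and
  sub-minimum sample sizes raise immediate, named errors.
* Fold assignment, inner-CV splits, permutations, generator draws and
  fixture weights all derive from explicit integer seeds through one
  sub-stream scheme; identical configuration and seeds reproduce every
  output file byte-for-byte, and no package function disturbs the
  caller's RNG state.

## Problem sizes used by the checks

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale, chosen as the smallest sizes at which each property
is statistically decisive: 1000 random vectors (lengths 2–500) for the
Gini oracle equivalence; $10^5$ draws for the distribution anchors;
$n = 2000$ images × 15 layers × 256 activations for parameter recovery
and null calibration; 200 replicate null datasets ($n = 100$, $B = 199$)
for test size; and 200 fixture images through the encoder with 10-fold
CV repeated 5 times for the end-to-end battery. The headline numbers of
the full-scale analysis (units of ~25% of beauty-score variance
explained by all-layer sparsity on real portrait/painting datasets)
require those external datasets plus pretrained VGG16 weights and are
deliberately not asserted anywhere.

## Known limitations

* The per-layer ridge family falls back to OLS when only one component
  is retained (glmnet requires $p \ge 2$); the battery records the
  actual per-layer predictor counts.
* The permutation null for ridge families conditions on the observed
  $\lambda$; a fully nested permutation null would be preferable in
  principle but is computationally out of reach at realistic $B$, and
  the size of the implemented test is verified empirically.
* The VGG16 adapter's forward pass is pure R and intended for
  correctness and moderate workloads, not for encoding thousands of
  high-resolution images; the architecture plan, not inference speed,
  is what the package's own analyses need from it.
* Treves–Rolls results are computed and written alongside Gini but the
  battery drivers analyze the Gini profile; the alternate metric exists
  to check qualitative agreement, mirroring its role in the field.
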
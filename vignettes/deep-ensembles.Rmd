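---
title: "Deep ensemble learning with pluggable core learning units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep ensemble learning with pluggable core learning units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepens)
```

## The model family

`deepens` implements three ensemble meta-algorithms for binary
classification in which every base learner is a trainable neural network —
a *core learning unit* (CLU). The same three constructions run on tabular
clinical records (MLP units), grayscale medical images (convolutional
units) and minute-resolution wearable-device recordings (gated recurrent
units with attention pooling):

* **Deep aggregated learning (DAL)** — bagging. Each of $n$ members is
  trained on its own bootstrap resample of the training set and the
  ensemble score is the mean of the member probabilities,
  $P = \tfrac{1}{n}\sum_{i=1}^{n} P_i$. Averaging reduces the variance of
  the individual networks without touching their bias.
* **Gradient deep-learning boosting (GDLB)** — gradient boosting with
  neural regression boosters. The running prediction starts at
  $P_\mathrm{base} = \bar{y}$ (the training-label mean); booster $i$ is fit
  by mean-squared error to the current residuals $y - P^{(i-1)}$ and its
  output enters the prediction scaled by a learning rate
  $\lambda_i \in (0, 1)$:
  $P^{(i)} = P^{(i-1)} + \lambda_i\,O_i(x)$. By default each $\lambda_i$ is
  one uniform draw from the run's seed; a fixed numeric rate can be given
  instead (and the boundary value $\lambda = 1$ is accepted so the
  one-step exact-correction identity can be exercised). The final score is
  the running prediction clipped to $[0,1]$ and thresholded at 0.5.
* **Deep stacked generalisation (DeSGEL)** — two-level stacking. $n$
  level-0 classifiers produce a *metadata* matrix whose columns are their
  scores; a level-1 classifier $f$ maps a metadata row to the final score,
  $P = f\{\cup_i P_i\}$.

Classifier units train with binary cross-entropy, a sigmoid output and the
Adam optimizer; boosting units train with mean-squared error, a linear
output and SGD, because their targets are real-valued residuals. The two
pairings are enforced by `clu_spec()`.

## The CLU engine

The package carries its own compact neural engine (dense, 3×3
convolution + 2×2 max-pool, and GRU-with-additive-attention layers with
reverse-mode gradients, Adam/SGD, and optional L2 weight decay on weight
matrices). Two training conveniences are built in:

* **Step-decay learning-rate schedule.** Every `lr_period` (default 50)
  completed epochs the rate is reduced by 10 %
  (`lambda <- lambda - lambda * 0.1`), so after $k$ decay points
  $\lambda_k = \lambda_0 \cdot 0.9^k$.
* **Best-validation-loss checkpointing.** The validation loss is evaluated
  after every epoch and the returned model carries the parameters of the
  epoch at which it was minimal, not necessarily the last.

Determinism is a contract: parameter initialisation is drawn from
`spec$seed`, batch shuffling from a stream derived from it, and all
computation is ordinary BLAS arithmetic, so the same spec and data give
bitwise-identical parameters, logs and predictions. Every analytic
gradient in the engine (dense, convolutional, recurrent, and the
autoencoder) is verified against central differences in the test suite.

Default architectures (all overridable through `layer_sizes`): MLP
64–32–1 for tabular rows; three 3×3-conv blocks of 16/32/64 filters with a
dense head for images; a single 64-unit gated recurrent layer with
additive attention pooling and a dense head for sequences. These defaults
are deliberately configurable — the framework, not one architecture, is
the point — and no claim is made that they match any particular published
architecture table.

## Phase 1: preprocessing

Each data type has a leakage-free chain; every fitted transform (scaler,
feature ranking, autoencoder) sees the training partition only, which the
suite asserts by perturbing test rows and checking that fitted parameters
are unchanged.

* **Tabular.** Missing entries are imputed with the per-feature mean of
  the observed values; features are standardised as
  $x_\mathrm{scaled} = (x - \mu)/\sigma$ with $\mu, \sigma$ (population
  form, $\div n$) computed on the training rows; a 100-tree random forest
  of depth-2 trees (via `ranger`) ranks features by impurity importance,
  normalised to sum to 1. Zero-variance features scale with $\sigma = 1$
  and a warning.
* **Sequential.** A missing minute is filled with the same participant's
  mean at the same minute-of-day across days (the mechanism matches
  device-off gaps, which recur at similar clock times); a minute missing
  on *every* day falls back to the participant's overall mean, staying
  within participant. Samples are then cut by a seven-day forward moving
  window: 10,080 consecutive minutes per sample, advanced one day per
  step, so a participant with $D$ whole days yields $D - 6$ samples, each
  inheriting the participant's label. An optional daily-profile reduction
  averages the seven values at each minute-of-day down to 1,440 values per
  window; the workflow additionally keeps every `minute_step`-th minute
  (default 30) so recurrent units see 48 steps — a desk-scale choice, not
  a statement about the method.
* **Image.** All images are resized (bilinear, via `EBImage`) to one
  grayscale working shape — 200×200×1 by canonical default, 32×32 in the
  workflow's desk-scale runs — with pixels clipped to $[0,1]$. For the
  classical comparators, which cannot consume pixels directly, a
  convolutional autoencoder (two conv+pool encoder blocks of 16/8 filters,
  a dense linear bottleneck, mirrored upsample+conv decoder, sigmoid
  pixels, MSE loss) is fit on the training images and its frozen
  bottleneck provides one fixed-length feature row per image. A dense
  bottleneck, rather than a bottleneck feature map, is used so the
  extracted dimension equals `bottleneck_dim` exactly regardless of image
  size.

Splitting follows the 80:4:16 train/validation/test ratio with
largest-remainder apportionment (ties broken train → val → test): the test
partition is drawn once and held fixed, and the remaining rows are
re-split into train/validation once per fold (default 10 folds). Repeated
experiments rotate over these folds while the test set stays untouched.

## Phase 2 and 3: tuning and evaluation

The hyperparameter grid sweeps the number of sub-models (canonically
5–50) and the epochs per sub-model (canonically 50–500, both in steps of
50); each grid point is scored by validation accuracy and ties prefer
fewer sub-models, then fewer epochs. Evaluation uses the confusion matrix
and its derived metrics — accuracy, precision, recall, F1 and the Matthews
correlation coefficient

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}$$

— plus AUC computed as the Mann–Whitney rank statistic (the probability
that a random positive outscores a random negative, ties counted ½),
which is identical to trapezoidal ROC integration in exact arithmetic but
simpler to verify against a brute-force pair count. Degenerate
denominators (no positive predictions; a zero factor under the MCC root)
return 0 with a warning. Repeated runs are summarised per metric as
"m ± d" with the mean and the population standard deviation across
repetitions, rendered at two decimals.

## Synthetic benchmark emulators

Three generators reproduce the *structural* properties of the benchmark
shapes the workflow targets, so the whole pipeline runs without any
external data:

* `hdu_like` — 270 × 13 tabular rows at class ratio 1.25
  (negative:positive), a handful of informative features shifted by a
  configurable effect size in the positive class, missingness completely
  at random;
* `xray_like` — variably sized grayscale images at class ratio 0.37,
  where positive images carry additive bright blobs over background noise;
* `depresjon_like` — tens of participants of minute-level activity at
  class ratio 2.05, built as baseline + class-dependent circadian
  (24-hour) sinusoid + noise, truncated at zero, with contiguous
  device-off missing segments (not i.i.d. points — the block structure is
  what stresses the time-of-day imputer).

Class counts are apportioned by largest remainder, so realised counts are
within one sample of the requested ratio. What passing tests on these
generators shows is that the machinery — imputation, windows, training,
aggregation, metrics — behaves exactly as specified on data whose
structure matches the benchmarks; it does not show clinical-level
performance, because the generators make no attempt to reproduce the real
datasets' covariance or label noise beyond shape, ratio, class signal and
missingness mechanism.

## Design choices that were genuinely open

* **DeSGEL metadata.** Training the meta-learner on the level-0 members'
  own training scores would leak their memorised fit. Two leakage-free
  constructions exist: scores on the validation split, and out-of-fold
  (OOF) prediction over the training set. With the 80:4:16 ratio the
  validation split is tiny (≈ 4 % of n), which is too few rows to estimate
  even the meta-learner's intercept reliably — on pure-noise data the
  stacked model then behaves like a coin flip rather than a
  majority-class predictor. The default is therefore classical OOF
  stacking (3 folds: each member is refit with one fold held out to score
  it, so every training row receives a leakage-free score from every
  member), with `metadata = "validation"` available as the cheaper
  option.
* **Meta-learner capacity.** The default level-1 classifier is a single
  sigmoid unit over the member scores — logistic regression, with mild L2
  decay — following the long-standing stacking advice that the combiner
  should be simple; it can at worst approximately select the best member,
  and it cannot overfit a modest metadata matrix the way a wider MLP can.
* **DAL subsets.** Bootstrap resamples of the full training size, the
  classical bagging construction; disjoint partitions and full-data
  members are options. Member $i$ uses seed $s + i - 1$, so ensembles are
  reproducible yet members distinct. Mode aggregation breaks even vote
  ties toward the positive class (deterministic, and conservative in a
  screening setting where a missed positive is the costlier error).
* **GDLB class conversion.** Regression output becomes a class by
  clipping the raw score to $[0,1]$ and thresholding at 0.5. Boosters
  should be *weak* learners (small layer sizes, short schedules): flexible
  boosters refit residual noise, which inflates score variance around
  $P_\mathrm{base}$ on uninformative data.
* **Numerical conventions.** Max-pool ties route the gradient to the
  first slice; split and class-ratio rounding both use largest remainder;
  sequence windows are positional (no calendar or daylight-saving
  handling); images are clipped, not renormalised, after interpolation.

## Problem sizes and limitations

The suite and the acceptance script run everything at desk scale by the
package's own choice: tabular learnability experiments use $n = 500$ rows
with a 16–8–1 MLP over 20 epochs and 5 sub-models per ensemble, repeated
10 times; image runs use 16–40-pixel synthetic images; sequential runs
use 48-step daily profiles. The canonical grid (up to 50 sub-models × 500
epochs) is expressible but not exercised by default.

Known limitations: binary classification only; one CLU kind per ensemble;
no GPU-scale architectures (a compact conv net stands where a deep
residual network would run at production scale); sequence windows are
split into train/validation/test as samples, so windows of one
participant can land on both sides of a split — participant-level
splitting would be the stricter protocol for clinical claims; and the
null-case behaviour of GDLB under random $\lambda$ is intrinsically
noisier than DAL's or DeSGEL's, since boosters chase residual noise.
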
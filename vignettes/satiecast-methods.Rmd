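---
title: "Predicting appetite VAS curves from satiety-hormone curves: models and methods"
author: "satiecast authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting appetite VAS curves from satiety-hormone curves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satiecast)
```

## The problem

After a meal (or an intestinal nutrient infusion), the gut releases the
satiety hormones GLP-1, CCK and PYY, whose plasma concentrations rise and
decay over a few hours. Over the same window, subjects report appetite on
100-mm Visual Analog Scales (VAS): desire to eat, hunger, fullness and
satiety. Crossover satiety trials measure both, for cohorts of roughly
13–15 volunteers sampled 9–10 times over 150–270 minutes.

satiecast learns the mapping from a subject's three whole hormone curves
to their four whole VAS curves, so that VAS responses can be predicted
for study arms where only hormones were measured — including arms where
one or two hormones are missing, or where hormone sampling stops earlier
than the prediction window. A prediction is treated as acceptable when
the Pearson correlation between predicted and measured cohort-average
VAS curves exceeds 0.85 for every VAS type.

## Data model

A study arm is a `SatietyStudy`, a `SummarizedExperiment` whose rows are
sampling times (minutes since the first sample), columns are subjects,
and whose seven assays are the three hormone channels (GLP-1 and CCK in
pmol/l, PYY in pg/ml) and the four VAS channels (0–100). A hormone
nobody measured for a subject is an all-`NA` column mirrored by a
logical availability flag in `colData`. Units are carried as metadata
and never converted: the networks consume normalised values, so mixed
units are harmless.

Long-format CSV (`study, subject, time_min, variable, value`) is the
interchange format; `writeStudy()` emits values with 17 significant
digits so `readStudy()` round-trips bit-exactly. When per-subject
sampling grids differ, all series are aligned by linear interpolation
onto a canonical uniform grid whose step is the median sampling interval
rounded to 5 min — linear interpolation is monotone-preserving and
parameter-free, and exact at the measured points. Resampling never
extrapolates; extending past the measured range is the extender's job
(below), so the two operations cannot be confused.

## Feature construction

One training sample is one subject's complete curve set. The network
input concatenates:

* the **temporal block**: the three hormone series and their four
  elementwise interaction products
  $[G\!\cdot\!C,\; G\!\cdot\!P,\; C\!\cdot\!P,\; G\!\cdot\!C\!\cdot\!P]$,
  in the fixed channel order $G, C, P, GC, GP, CP, GCP$;
* the **spectral block**: the Thomson multitaper power-spectral-density
  estimate of each of the same seven channels.

With $T$ grid points and $F = \mathrm{nfft}/2 + 1$ frequency bins the
input length is $7T + 7F$; the output is the four concatenated VAS
curves, length $4T$.

The multitaper estimate averages $k$ eigenspectra
$dt\,|\mathrm{DFT}(v_j \circ x)|^2$ over unit-energy discrete prolate
spheroidal (Slepian) tapers $v_j$; interior bins are doubled so the
one-sided estimate integrates to the total power. The tapers are
computed from the standard symmetric tridiagonal eigenproblem. Defaults
are the canonical Thomson settings $nw = 4$, $k = 2nw - 1 = 7$, with
`nfft` the next power of two at or above $T$; the frequency unit is
cycles/min, derived from the grid step. Channels are mean-centered
before the PSD (the DC term would otherwise dominate every spectral
feature) while the temporal block keeps raw concentrations; centering
sits behind a settings flag, and `multitaperPSD()` itself does not
center, so a constant series correctly concentrates its power at zero
frequency.

One numerical subtlety is documented here because tests rely on it: the
$k$-taper average has a deliberately flat-topped spectral window of
half-width $nw$ frequency bins, so the *single-bin* location of a peak
within that band is decided by ripple. Exact-bin peak placement holds
for the concentrated single-taper estimate ($k = 1$); the $k = 7$
default localises a pure tone to within $nw$ bins by design. Tests pin
both statements separately. No adaptive (Thomson-weighted) combination
and no cross-spectra are computed.

## The network core

All networks are multilayer feed-forward perceptrons with the
log-sigmoid activation $\mathrm{logsig}(x) = 1/(1+e^{-x})$ on every
layer: $H = \mathrm{logsig}(U w_1 + b_1)$,
$Y = \mathrm{logsig}(H w_2 + b_2)$, with one bias per node (a
`sharedBias` switch ties each layer's biases to a single scalar, the
literal one-scalar-per-layer reading). Because outputs live in $(0,1)$,
every channel is scaled linearly into $[0.1, 0.9]$ using bounds fitted
on training data only; inversion is exact, zero-range channels map to
the midpoint, and de-scaled predictions are clamped at the fitted
bounds (so VAS predictions always lie in $[0, 100]$).

Training minimises full-batch mean squared error by backpropagation.
The default optimiser is resilient backpropagation (iRprop\-):
per-parameter sign-based steps (grow 1.2, shrink 0.5, step bounds
$10^{-9}$–$1$), which is deterministic, insensitive to gradient
magnitude and reaches the accuracy the deterministic recovery checks
demand within a few thousand epochs; plain gradient descent with
momentum (0.9, learning rate 0.1) is available as
`algorithm = "gdm"`. Weights initialise uniform
$\pm 1/\sqrt{\mathrm{fan~in}}$ from the explicit config seed.

Regularisation is validation-based early stopping: a single random
split (default 20% validation) by the config seed, keeping the
parameters with the lowest validation MSE and stopping after 100 epochs
without improvement (budget 4000 epochs). With cohort-sized training
sets of 26–45 whole-curve samples, early stopping — not architecture —
is the regulariser that matters; k-fold schemes are intentionally out
of scope. Hidden widths default to two layers of 10 for the VAS and
imputation networks and one layer of 10 for the series extender; widths
are defaults, not claims. Identical data, config and seed reproduce
identical parameters, and the generator and training keep private RNG
streams so library calls never perturb a caller's randomness.

The backpropagated gradient is verified against central finite
differences (relative error below $10^{-6}$), and the forward pass
against an explicit per-node scalar loop, in the test suite.

## Imputing missing hormones

The imputer is one shared two-hidden-layer network from any *single*
hormone curve (length $T$) to the full triple $[G, C, P]$ (length
$3T$). Each complete training set contributes exactly three
presentations — its G, its C and its P curve, each paired with the full
triple as target — so $n$ complete sets give $3n$ pooled pairs. The
input carries no identity tag (an optional one-hot tag exists behind a
config flag, default off), and input scaling uses a single range shared
across all three hormones: per-hormone ranges differ by an order of
magnitude, and per-channel scaling would leak the input's identity
through its magnitude. The network therefore disambiguates hormones by
their characteristic magnitudes and shapes. Outputs are de-scaled and
clamped non-negative. When a subject has two measured hormones, each is
imputed independently and the predictions for the missing channel are
averaged — the symmetric choice; measured channels are never
overwritten. Every fill is recorded in the study's provenance metadata.

## Extending short series

The extender learns the one-step map from the trailing lag window
$[X(t-L), \dots, X(t-1)]$ to $X(t)$, pooling pairs over all training
curves of one hormone channel (one model per channel); each series of
length $n$ yields $n - L$ pairs. The minimal form uses only the single
value $X(t-L)$ and is available as `singleLag = TRUE`, but a scalar lag
cannot represent rise-then-decay shapes, so the default input is the
full window with $L = 2$. Extension is closed-loop: each new value is
predicted from the trailing window of observed and previously predicted
values and appended until the prescribed length; the observed prefix is
returned untouched, and appended values are clamped to the training
value range, so a learned contraction stays bounded. In the pipeline
the extender brings short *hormone* curves onto the model grid; VAS
curves are predicted, never extended.

## Pipeline and evaluation

`predictVas()` applies, per subject and only as needed: (1) closed-loop
extension of hormone curves that stop before the model grid, (2)
imputation of missing channels, (3) feature assembly, the forward pass,
and de-scaling to 0–100. Provenance metadata records which subjects
and channels were extended or imputed; a complete study on the model
grid passes through with empty provenance.

Evaluation follows the cohort-average protocol: predicted and measured
studies are averaged over subjects (each channel over the subjects for
which it is available), then the Pearson correlation over time points
is computed per VAS type, with the sample ($n-1$) formulation. A
zero-variance averaged curve makes $r$ undefined; it is reported as
`NA`, never coerced to a number. Pooled per-subject-point correlation
is deliberately not the default, matching the cohort-average reporting
convention; note that subject averaging removes independent measurement
noise, so cohort-level $r$ is systematically higher than per-subject
$r$ would be.

The hormone-ablation table rebuilds the test set for each of the seven
non-empty subsets of {GLP-1, CCK, PYY} (rows `a`–`g`: G; G,C,P; G,C;
G,P; C,P; C; P), masks the complement, imputes, predicts with the
*same* trained model, and evaluates. Re-using the model rather than
retraining per subset isolates the information content of the supplied
hormones from training variance.

## The synthetic-study generator

Real cohorts of these designs are small, proprietary and rarely
deposited, so the package carries a generator that emulates their
statistical structure with a known ground truth; it is a statistical
stand-in, not a gut-physiology model.

Hormone $h$ of subject $i$ follows
$$x_{ih}(t) = b_h\,m_{ih} + a_h\,\phi\,f_{ih}\,
  g\!\left(t;\, t_{p,h}\,s_{ih}\right) + \varepsilon,$$
where $g(t; t_p) = z^{\alpha} e^{\alpha(1-z)}$, $z = (t-t_0)/t_p$, is a
gamma-shaped response (zero before meal onset $t_0$, peak 1 at
$t_0 + t_p$, shape $\alpha = 2$), $\phi$ is a per-study food-effect
multiplier, $\varepsilon$ is Gaussian measurement noise and negative
draws are clamped at zero. The subject effects $m_{ih}, f_{ih}, s_{ih}$
(baseline, amplitude, timing) are lognormal (sdlog 0.1, 0.2, 0.1) drawn
independently per subject *and per hormone*: that independence is what
makes each hormone carry partly subject-specific information, so that
removing a channel genuinely discards signal and ablation orderings are
meaningful. Defaults mimic realistic scales — GLP-1 baseline 8,
amplitude 12 pmol/l, peak 45 min; CCK 2/4 pmol/l, 30 min; PYY 90/60
pg/ml, 60 min; noise roughly 5% of amplitude — so the scaling code is
exercised across magnitudes.

Ground-truth satiating scores are
$$V(t) = 100\,\mathrm{logsig}\!\big(\beta_0 + \beta_G \hat G +
  \beta_C \hat C + \beta_P \hat P + \beta_{GCP}\hat G \hat C \hat P\big),$$
on noiseless hormones normalised by their population reference range
$(x - b_h)/a_h$ (normalising per subject would cancel the very
amplitude effects the model should learn). Satiety and fullness have
their own weights, with a non-zero triple-interaction term so the
interaction features are informative by construction; hunger and desire
are their exact complements ($100 - \cdot$), and observed VAS adds
Gaussian noise (sd 3) clamped to $[0, 100]$. `gDominantWeights()`
switches to a mapping driven by GLP-1 alone, used to probe ablation
rankings. Canonical availability scenarios (`complete`,
`missing_cck`, `glp1_only_short` at 2/3 of the grid) reproduce the
standard study roles.

What passing tests on this generator do **not** show: real hormone–VAS
coupling is noisier, non-stationary and partly subject-specific in ways
no fixed mapping captures; cohort-average correlations near 0.999 on
synthetic data say the pipeline recovers a recoverable mapping at these
study sizes, not that real studies will reach any particular value.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the package at the
study sizes the designs describe: 15-subject arms on a 0–270 min grid
with 15-min steps ($T = 19$, `nfft` 32, feature length 252), training
sets of 30 whole-curve samples, imputer cohorts of 50–60 sets, and an
AR(1) series of 40 points for the extender; the end-to-end run takes a
few seconds on one CPU. Degenerate inputs are handled explicitly:
constant channels scale to the midpoint and invert to the constant,
all-zero curves stay finite and non-negative through the imputer, and
`nnTrain()` refuses fewer than 4 samples or a non-finite loss rather
than returning silently broken parameters.

## A worked example

```{r example, eval = FALSE}
trainA <- simulateStudy(simulationConfig(seed = 7, name = "train-A"))$study
trainB <- simulateStudy(simulationConfig(seed = 8, foodEffect = 1.5,
                                         name = "train-B"))$study
test <- simulateStudy(simulationConfig(seed = 11, name = "test"))$study

model <- trainVasModel(list(trainA, trainB), trainingConfig(seed = 1))
imputer <- trainImputer(list(trainA, trainB), trainingConfig(seed = 2))

# a test arm missing CCK, as in two-hormone study designs
pred <- predictVas(model, maskHormones(test, c("GLP1", "PYY")),
                   imputer = imputer)
evaluateVas(pred, test)
```

## Known limitations

* Whole-curve vectorisation fixes the grid length at training time;
  test arms are resampled (and, if short, extended) to that grid, and
  sparse test sampling near a VAS peak will blunt the predicted apex.
* The imputer's identity-free design is ambiguous in principle when two
  hormones overlap in magnitude and shape; the shared-range scaling
  keeps the hormones separated only as long as their physiological
  ranges are.
* Early stopping with a single random split is the only regulariser;
  with very few subjects the validation split is small and the stopping
  point correspondingly noisy.
* Correlation on cohort-averaged curves is a lenient statistic; use the
  pooled mode for per-subject claims.
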
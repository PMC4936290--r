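# satiecast

Neural-network prediction of appetite VAS time courses from plasma
satiety-hormone curves.

## What this is for

In satiety trials, volunteers eat a meal (or receive a gastric/ileal
nutrient infusion) and are then followed for 2.5–4.5 hours: blood
samples give the plasma curves of the gut satiety hormones **GLP-1**,
**CCK** and **PYY**, while the volunteers score their appetite on
100-mm Visual Analog Scales (**VAS**) — desire to eat, hunger, fullness
and satiety. Hormone assays are objective but appetite is what trials
ultimately care about; conversely, many study arms have VAS scores but
incomplete hormone panels, or hormone sampling that stops early.

satiecast is for researchers analysing such trials. It learns the map
from a subject's whole hormone curve set to their four whole VAS
curves, and handles the two practical gaps of real datasets: missing
hormone channels (via an imputation network) and short sampling windows
(via an autoregressive series extender). A built-in synthetic-study
generator with known ground truth makes the entire pipeline testable
without access to clinical data.

## The model

All networks are multilayer feed-forward perceptrons with log-sigmoid
activation on every layer,

    H = logsig(U w1 + b1),   Y = logsig(H w2 + b2),   logsig(x) = 1/(1+e^-x),

trained by full-batch backpropagation (resilient backpropagation by
default) with validation-based early stopping.

For the VAS network, the input for one subject is

    U = [ I(t), M(t), I(w), M(w) ]

where `I(t) = [G(t), C(t), P(t)]` are the hormone curves,
`M(t) = [G*C, G*P, C*P, G*C*P]` their elementwise interaction products,
and `I(w), M(w)` the Thomson multitaper power-spectral-density
estimates (DPSS tapers, nw = 4, k = 7) of the same seven channels; the
output is `Y = [Vd(t), Vh(t), Vf(t), Vs(t)]`, the four concatenated VAS
curves. The imputer maps any single hormone curve `X(t)` to the full
triple `[G(t), C(t), P(t)]`, trained with three presentations per
complete set (G, C and P each shown at the input). The extender learns
`X(t)` from the lag window `X(t-L)..X(t-1)` and continues short curves
closed-loop to a prescribed length.

Predictions are evaluated by the cohort-average protocol: Pearson r
between subject-averaged predicted and measured curves, per VAS type,
with r > 0.85 for all four types as the acceptability bar.

## A worked example

Train on two simulated 15-subject study arms (the second with a
stronger food effect), then predict VAS for a held-out arm in which CCK
was never measured — the imputer fills it from GLP-1 and PYY:

```r
library(satiecast)

trainA <- simulateStudy(simulationConfig(seed = 7, name = "train-A"))$study
trainB <- simulateStudy(simulationConfig(seed = 8, foodEffect = 1.5,
                                         name = "train-B"))$study
test   <- simulateStudy(simulationConfig(seed = 11, name = "test"))$study

model   <- trainVasModel(list(trainA, trainB), trainingConfig(seed = 1))
imputer <- trainImputer(list(trainA, trainB), trainingConfig(seed = 2))

pred <- predictVas(model, maskHormones(test, c("GLP1", "PYY")),
                   imputer = imputer)
evaluateVas(pred, test)
#> EvaluationReport for "test" (15 subjects)
#>   desire   r = 0.998
#>   hunger   r = 0.996
#>   fullness r = 0.997
#>   satiety  r = 0.997
#>   average  r = 0.997
```

Each `r` is the Pearson correlation between the cohort-averaged
predicted and measured curve of one VAS type over the 19 time points of
the 0–270 min grid; 0.996–0.998 means the predicted cohort curves are
nearly indistinguishable from the measured ones even though CCK was
imputed. `hormoneAblation(model, imputer, test)` repeats the evaluation
for all 7 hormone subsets, and `metadata(pred)$provenance` records
which channels were imputed or extended for which subjects.

A thin command-line wrapper over the same functions ships at
`inst/cli/satiecast` (`simulate`, `train-vas`, `train-imputer`,
`train-narx`, `predict`, `evaluate`, `ablation`), reading and writing
the long-format CSV of `readStudy()`/`writeStudy()`.

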
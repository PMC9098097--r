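---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ftirlung)
```

This vignette is the package's account of its science: the models it
implements, the tunable parameters with their defaults and units, what the
synthetic generator does and does not emulate, the numerical choices, and
the design decisions that were genuinely open.

## The data and its conventions

A spectral dataset is a wide tibble: one row per measured spectrum, columns
`id`, `label` (`benign`/`malignant`/`unknown`) and one numeric column per
wavenumber.  The canonical grid is 462 equally spaced points from 1800 down
to 850 cm⁻¹ (step 950/461 ≈ 2.06 cm⁻¹) — stored high→low, the export
convention of FTIR instruments; 462 points and "~2 cm⁻¹ steps" are only
jointly satisfiable by this equispaced construction.  Cropping to the
fingerprint region uses a closed interval so the endpoints 1800 and 850
stay in range.  CSV round-trips preserve at least 12 significant digits.

## Preprocessing

**Peak normalisation** (default `minmax`) maps each spectrum to
`(x − min x)/(max x − min x)`, so every spectrum spans [0, 1] — the scale on
which the band amplitudes below are defined.  A `literal` mode divides by
`max x` instead of the range, for compatibility with the alternative
transcription of the same rescaling; it is not the default because the band
amplitude table presumes the [0, 1] span.  **Z-score normalisation**
centres and scales each spectrum to mean 0, SD 1 (sample SD), and is the
normalisation applied to classifier training inputs, as recommended for
SELU networks.  Both are strictly per-spectrum: no other row influences the
result.

**Rubber-band baseline correction** subtracts the lower convex hull of the
points (wavenumber, absorbance).  The hull is seeded by splitting the
ascending axis into `n_baseline_points = 64` equal segments and taking each
segment's minimum (plus both endpoints); any point still below the
resulting envelope is added and the hull recomputed until none remains.
The converged envelope equals the lower convex hull of the whole spectrum —
a fixed point independent of the seeding — which is what guarantees the
three properties a baseline must have: the corrected spectrum is
non-negative, touches zero at every anchor, and is *exactly* invariant to
adding any linear ramp (a hull is preserved by shear).  A construction that
interpolates only the 64 segment minima has none of these guarantees:
segment argmins move under a ramp, and non-candidate points can fall below
the candidate hull.  That is why the segmentation here only seeds the hull.

**Outlier screening** scores each sample by the mean over grid points of
the absolute difference to its class's pointwise-median spectrum, divided
by the class median of that deviation; samples scoring above
`threshold_mads = 3.5` are removed.  The *mean* (not the median) across
grid points is deliberate: absorption bands cover only part of the
fingerprint grid, so a sample whose peaks are grossly aberrant can still
have an ordinary between-band baseline — a median-based deviation sits at
the in-band/out-of-band boundary and separates poorly (measured on the
five-fold amplitude fixture: median-based scores 1.8–5.4 against a typical
maximum of 2.5; mean-based scores ≥ 11 against ≤ 2.3).  An explicit
`exclude_ids` override exists for audited removals.

## The synthetic generator

No patient spectra are publicly deposited, so every downstream stage is
exercised on synthetic cohorts whose statistical structure mirrors the
published band table: nine Gaussian absorption bands at the tabulated
class-specific positions, with per-spectrum amplitudes drawn from the
tabulated class-conditional mean ± SD (truncated at zero — absorbances are
non-negative and the weak bands have large relative SDs), plus a random
linear drift of magnitude ≤ `baseline_amplitude` and white noise of SD
`noise_sd`, clipped at zero.

Parameter defaults, chosen once:

* **Band width 12 cm⁻¹** (Gaussian SD).  The band table carries no width
  information; 12 cm⁻¹ keeps the closest tabulated neighbours resolvable
  on the 462-point grid while giving bands realistic ~25–30 cm⁻¹ visual
  width.
* **`baseline_amplitude = 0.05`, `noise_sd = 0.01`** (absorbance units on
  the normalised scale): residual drift of a few percent of the strongest
  band and ~1 % white noise are typical of baseline-corrected,
  peak-normalised tissue spectra at 48 co-added scans.
* **Amplitude correlation 0.5** between the glycogen (1051/1030) and
  phosphorylated-protein (880/878) bands, mirroring their observed positive
  covariation; all other band amplitudes are drawn independently, because
  only marginal summaries are published — the true within-class covariance
  is unknowable from them.  This is the generator's main simplification:
  real spectra share global intensity factors across *all* bands, exhibit
  correlated (non-white) noise, and contain scattering artefacts that no
  sum of independent Gaussians reproduces.  Tests passing on this generator
  therefore demonstrate correctness of the *algorithms*, not clinical
  performance.
* **Cohort defaults 56 malignant / 66 benign** (the study cohort);
  deviant spectra are injected with five-fold band amplitudes, labelled 3
  malignant per 1 benign — the composition of the four spectra removed
  from the study cohort (122 → 118 = 53 + 65).
* The **pseudo-clinical fixture** draws 94 concordant spectra (42
  malignant, 52 benign) at the standard effect sizes and 24 discordant
  spectra (11 malignant, 13 benign) whose band means and SDs are shifted a
  fraction `ambiguity` (default 0.5, i.e. halfway) toward the opposite
  class, emulating tissue on which pathologists disagree.

Because the tabulated amplitudes are *already* peak-normalised values, the
generator's output is on the normalised scale; analyses that re-normalise
divide by the (random) strongest-band amplitude and thereby add
multiplicative noise.  The peak-statistics acceptance checks therefore read
the generated spectra natively.

## Peak statistics

Visual peak picking is operationalised as topographic-prominence detection
(default `min_prominence = 0.02` on peak-normalised spectra) on each
class's median spectrum.  Malignant and benign peaks are paired greedily by
nearest position within `pairing_tolerance = 25` cm⁻¹ (the largest
tabulated within-band class offset is 21 cm⁻¹).  Per-sample absorbances are
read at each class's own peak position — exact-position readout, matching
the two position columns of the band table; a local-max readout would bias
absorbances upward under noise.  Group comparison uses a two-tailed
Mann–Whitney U with midrank ties: complete enumeration of assignments for
groups of ≤ 8 (exact, ties included), otherwise the normal approximation
with tie correction.  The Shapiro–Wilk gate wraps `stats::shapiro.test`
(Royston's algorithm) and only informs the parametric/non-parametric
choice.

Statistical power note: at the tabulated 1314/1312 marginals
(0.1334 ± 0.0582 vs 0.1711 ± 0.0591) and group sizes 53/65, the
Mann–Whitney test's power is ≈ 92 % — this band is intrinsically the
hardest of the four between-class bands to flag, and no generator setting
can raise that ceiling, which is set by the published means and SDs.

## PCA

The scatter matrix `(X − X̄)ᵀ(X − X̄)` is eigendecomposed exactly as
written — unnormalised, no 1/(N−1); explained fractions are
ratio-based and unaffected.  Eigenvector sign is fixed (largest-magnitude
entry positive) for reproducibility.  Scores are projections of centred
spectra on the top-two eigenvectors.  Peak-normalised spectra are the
default input for visualisation, z-scored spectra for model-adjacent use.

## Classical models

All six are implemented from first principles and share one contract:
`predict()` returns the probability of malignancy; the label is malignant
above 0.5.

* **LDA** — Fisher's criterion; for two classes the discriminant solves
  `S_W w ∝ μ_M − μ_B`.  With 462 variables ≫ samples, `S_W` is singular,
  so a ridge of `1e-6 · tr(S_W)/p` is added.  The probability is the
  softmax of the two Gaussian *density values* at the projected point,
  both with SD equal to the distance between projected class means.
* **SVM** — linear soft margin, `λ‖w‖²/2 +` mean hinge, per-sample SGD
  (λ = 1e-3 by default; the objective's constant is otherwise
  unspecified), 50 epochs; learning rate grid-searched on validation
  accuracy with ties to the smaller rate; Platt sigmoid fitted by damped
  Newton to training decision values with the regularised targets
  `(N₊+1)/(N₊+2)` and `1/(N₋+2)`.
* **Logistic regression** — sigmoid linear model, SGD on binary
  cross-entropy, zero initialisation (so the untrained model outputs 0.5),
  same grid search.
* **Decision tree** — CART with the Gini diversity index; thresholds at
  midpoints between adjacent sorted distinct values, ties to the lowest
  threshold; a split is accepted only if whole-tree validation accuracy
  does not decrease.  Leaf probability is the malignant training fraction,
  so an exactly tied leaf predicts benign (favouring specificity).
* **Random forest** — bagged CART trees; probability is the malignant vote
  fraction; tree count grid-searched (full grid 3–100) on mean validation
  accuracy over repeats, ties to the smallest count.
* **Naive Bayes** — every variable binarised at its Gini-optimal
  threshold; variables ranked by ascending impurity and added from k = 3
  upward to a Bernoulli model with add-one smoothing, stopping when
  validation accuracy decreases.  The fit is deterministic given the data,
  so the `trials` argument defaults to 1; it exists for callers who
  resample between repeats.

## Neural networks

Three families share a core: SELU activations
(λ ≈ 1.05070099, α ≈ 1.67326324) everywhere except a two-unit softmax
head; LeCun-normal weight initialisation (SD `1/√fan_in`, the standard
companion of SELU — the design notes say only "Gaussian"); zero biases;
per-sample SGD with AdaGrad (`G += g²`, step `−LR·g/(√G + ε)`); binary
cross-entropy on the softmax's malignant component (for two classes this
equals the full cross-entropy); alpha-dropout on dense hidden layers
during training only.

* **FNN** — `depth` ∈ {2, 4, 8} dense layers of `neurons` units.
* **RNN** — the input is cut into `partitions` contiguous chunks of size
  `⌈462/partitions⌉` (last chunk zero-padded) and fed through a single
  gate-free recurrent layer `h_t = selu(W_x·chunk_t + W_h·h_{t−1} + b)`,
  `h_0 = 0`; the final state passes through one dense SELU layer.  No
  gating is used because none is described for the single-layered design;
  dropout is applied to the dense layer only, not inside the recurrence
  (backpropagation through 10–100 steps under 90 % dropout would make
  gradients useless).
* **CNN** — `conv_layers` valid (unpadded) 1-D convolutions with a common
  `filter_size` and stride `filter_skip`, kernel count `base_kernels ·
  2^(layer−1)` (cumulative doubling per layer), no pooling; the flattened
  output feeds one dense SELU layer.  Layer lengths follow
  `⌊(L − filter)/stride⌋ + 1`; an architecture whose length falls below 1
  is rejected as invalid.

**Dropout rate.**  `dropout_rate = 0.9` — a *drop* probability of 90 % —
is the default, following the design account that attributes reduced
training capacity to the dropout's severity; the self-normalising-network
literature recommends small drop rates (0.05–0.10), which remain available
via the argument.  A practical consequence, visible throughout the tests:
under 90 % alpha-dropout the trained network's *ranking* of samples is
excellent (test AUC ~1 on separable synthetic data) long before its softmax
probabilities calibrate around the 0.5 threshold, because the train-time
activation transform biases the inference-time logits.  This also
reproduces the reported phenomenon of validation accuracy exceeding
training accuracy.  Threshold metrics (ACC, PPV, …) therefore lag AUC for
the networks at small training scales.

Gradients for all three families are analytic and verified against central
finite differences to 1e-5 relative error.  All training is bit-reproducible
from a seed.

## Genetic algorithm

Genomes hold the family's tunable hyperparameters, bounded as: epochs
[10, 300]; learning rate and AdaGrad ε as `10^−k`, k ∈ [0, 7] (drawn
log-uniformly); dense width [2, 30]; RNN partitions [10, 100] and fold
width [2, 30]; CNN conv layers [1, 5], filter size [2, 11], skip
[2, filter_size] (repaired by clamping after crossover/mutation), base
kernels `2^k`, k ∈ [1, 5].  Evolution follows the elitist scheme: 30
individuals, 30 generations; rank by validation accuracy; the fittest half
survives unchanged, and each elite mates with a partner drawn uniformly
from the *whole* population (the scheme is ambiguous between elite-only
and population-wide partners; population-wide keeps more diversity) to
produce the replacement bottom half via single-point crossover; the new
bottom half is mutation-eligible (5 % whole-genome replacement) before its
first evaluation.  Fitness values are cached by genome, since elitism
re-presents identical genomes every generation; a genome whose training
errors scores 0 rather than aborting the run.  Elitism makes the
best-fitness series non-decreasing by construction — a property the tests
assert on every run.

`desk_ga_config()` (population 8, 5 generations, epochs capped at 60) is
the reduced-scale preset used by the test suite and for interactive work;
the full-scale settings are the default.

## Evaluation protocol

The stated protocol — "stratified 10-fold cross-validation" *and* 70/15/15
splits — is internally inconsistent (ten equal folds cannot produce
70/15/15), and the aggregation formulas index fold n ≤ 10 within trial
t ≤ 50 with sets "randomly reselected for each trial".  The resolution
implemented: per trial, 10 *independent* stratified random 70/15/15
splits; 50 trials.  Per-class sizes are rounded (53 → 37/8/8,
65 → 46/10/9), so every set's class ratio matches the cohort's within one
sample.  The overall mean of a metric is the mean over trials of per-trial
fold means; the overall SD is the mean over trials of per-trial fold SDs —
exactly as the aggregation formulas are written, which is *not* the pooled
SD; a `pooled = TRUE` option emits the pooled version since the published
tables could be either.  AUC is the trapezoidal ROC area, with tied
probabilities grouped (equivalently: the rank-sum probability with half
credit for ties); the decision threshold is fixed at 0.5 throughout.
Zero-denominator ratios are recorded as missing and excluded from
aggregation.  Model comparisons report the difference of overall means
with a two-sided Mann–Whitney p-value on per-trial fold means — the
comparison test is unnamed in the source design; Mann–Whitney keeps the
package's nonparametric convention.

## Pseudo-clinical procedure

Each tuned design per family is retrained `runs` times (fresh seeds) on
the concordant set; every instance predicts every discordant sample, giving
designs × runs probabilities per (family, sample) — 500 at study scale.
The headline summary is the *median* with quartile bands (matching the
median-and-range presentation of the procedure); the arithmetic mean is
also emitted.  A sample is flagged `confident` when its median probability
toward the predicted class is ≥ 0.8 (the reported confidence bar) *and*
its interquartile range is ≤ 0.25; both are arguments.

## Problem sizes used by the tests

The suite exercises full study dimensions (462-point grid, 53/65 cohorts)
wherever a single fit suffices, and reduced dimensions (120-point grid,
~40-spectrum cohorts, short epochs, GA preset 8 × 5) for repeated-fit
calibration checks: Mann–Whitney type-I error over 2000 null simulations;
chance-level AUC of all 11 models over 20 seeds of a class-identical
generator; band-significance rates over 100 study-sized cohorts; and a
20-seed stub-fitness GA optimum check.  These sizes are the package's
testing choices; all full-scale settings remain the defaults.

## Known limitations

* The generator's independence of band amplitudes (beyond one programmed
  correlation) understates the covariance structure of real tissue
  spectra; classifier ceilings on synthetic data are optimistic.
* The published per-model performance values are shipped as reference data
  (`reference_performance()`) and cannot be recomputed without the
  undeposited patient spectra.
* Severe alpha-dropout biases probability calibration at small scales (see
  above); users who need calibrated probabilities from the networks should
  lower `dropout_rate` or recalibrate on validation data.
* The Mann–Whitney exact path enumerates all assignments only for groups
  of ≤ 8; beyond that the tie-corrected normal approximation is used
  without continuity correction.
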
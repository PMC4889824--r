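---
title: "Classifying hand gestures from two-channel surface EMG"
author: "gesturekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying hand gestures from two-channel surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gesturekit)
```

## The problem

Surface electromyography (SEMG) records the electrical activity of muscles
through skin electrodes. A recurring engineering task is to translate a short
window of SEMG signal into a discrete hand gesture, for prosthesis control,
rehabilitation interfaces and similar man–machine systems. `gesturekit`
implements a complete pipeline for the six-gesture, two-channel setting:
hand closing (HC), hand opening (HO), wrist flexion (WF), wrist extension
(WE), index-finger straightening (IF) and thumb straightening (T), recorded
from a flexor-site and an extensor-site electrode on the forearm.

The pipeline has four stages:

1. **Segmentation** — the recording is cut into consecutive non-overlapping
   windows (`sliding_segments()`). Short windows keep real-time latency low;
   windows under about 200 ms carry enough information that non-overlapping
   segmentation loses nothing, which is why the default is 187.5 ms. At the
   16 Hz envelope rate of a two-channel clinical device that is exactly
   `round(0.1875 * 16) = 3` samples per window.
2. **Feature extraction** — each window is summarised by classical
   time-domain features (`mav()`, `wl()`, `wamp()`, `ssc()`). Frequency and
   wavelet representations are deliberately out of scope: for this class of
   signal they add computational load without a classification benefit.
3. **Classification** — a soft-margin kernel SVM in a one-against-all
   arrangement (`train_ova()`): one binary machine per gesture, aggregated
   by the largest real-valued decision score.
4. **Model selection** — a Cuckoo Search metaheuristic (`cs_optimize()`)
   picks the kernel family (quadratic, polynomial or RBF) and its
   parameters by maximising the 10-fold cross-validated classification
   rate, breaking exact ties by the number of support vectors.

## Time-domain features

For a window $x_1, \dots, x_N$:

$$\mathrm{MAV} = \frac{1}{N}\sum_{i=1}^{N} |x_i|, \qquad
  \mathrm{WL} = \sum_{i=1}^{N-1} |x_{i+1} - x_i|,$$

$$\mathrm{WAMP} = \#\{\, i : |x_i - x_{i+1}| \ge \theta_W \,\}, \qquad
  \mathrm{SSC} = \#\{\, i : (x_i - x_{i-1})(x_i - x_{i+1}) \ge \theta_S \,\}.$$

The two indicator thresholds are a convention choice the classical feature
definitions leave open. `gesturekit` uses *greater-or-equal* indicators with
two independent thresholds:

* `wamp_threshold` ($\theta_W$, signal units). Because the device's
  amplitude units are arbitrary, the default is scale-adaptive: 5% of the
  median per-channel MAV of the segment set the configuration is resolved
  against (`resolve_feature_config()`). The threshold is resolved **once**,
  before any train/test splitting, and then treated as a fixed
  preprocessing constant; re-estimating it inside every split would change
  the feature definition between repeats for no practical benefit (it is a
  median over thousands of windows, so its sampling variability is
  negligible).
* `ssc_threshold` ($\theta_S$, squared units). Default $10^{-12}$ — a
  machine epsilon rather than zero, so that exact-zero products produced by
  repeated samples (common in quantised device streams) are not counted as
  slope reversals.

Feature vectors are laid out channel-major (`ch1` features, then `ch2`
features), so a model's weight layout is stable across configurations. A
z-score normalizer (`fit_normalizer()`) is available but off by default;
the classifier operates on raw device units unless asked otherwise.

## The one-against-all SVM

Each gesture gets its own binary soft-margin SVM (that gesture versus the
other five), solved by the libsvm dual solver from `e1071` — the
contribution here is the surrounding machinery, not a bespoke QP. Three
kernel families are supported, parameterised as

$$k_{\mathrm{quad}}(u,v) = (\gamma \langle u,v\rangle + c_0)^2, \quad
  k_{\mathrm{poly}}(u,v) = (\gamma \langle u,v\rangle + c_0)^d, \quad
  k_{\mathrm{rbf}}(u,v) = e^{-\gamma \|u-v\|^2},$$

with "quadratic" pinned to the polynomial family at degree 2. Prediction
takes the label whose machine returns the largest decision value; exact
ties go to the earlier label in the class list, so prediction is
deterministic. The 1:5 class imbalance of the relabelled binary problems is
left unweighted by default (an inverse-prevalence flag exists), matching
common practice for this setting.

Two accuracy conventions are implemented, because per-gesture benchmark
tables are readable either way: the default reports each class's own
one-vs-rest binary rate (`per_class_binary_rate()`), the alternative
(`rate_type = "multiclass_recall"`) reports per-class recall of the
aggregated multiclass prediction. The headline multiclass accuracy
(`multiclass_rate()`) is reported alongside either.

Support vectors are counted as training points with nonzero dual
coefficient, summed over the six binary machines for a total and divided by
the number of classes for the per-class mean — the quantity the optimiser
uses to break fitness ties, because fewer support vectors mean a simpler,
faster, better-generalising boundary.

## Cuckoo Search model selection

The search space mixes an integer kernel index and degree with real
parameters: $\gamma \in [2^{-15}, 2^3]$ and $C \in [2^{-5}, 2^{15}]$ on a
log10 scale, $c_0 \in [0, 10]$ linear, degree $\in \{2,\dots,5\}$. Integer
dimensions live on the real line internally and are rounded after clipping;
log-scaled dimensions keep the search uniform in the exponent, the natural
geometry for SVM hyperparameters.

Each iteration, every nest proposes a new candidate by a Lévy flight toward
the incumbent best,

$$x' = x + s \cdot L_\alpha \odot (x - x_{\mathrm{best}}),$$

with $L_\alpha$ drawn by the simplified Mantegna construction
$u/|v|^{1/\alpha}$, $u \sim N(0, \sigma_u^2)$, $v \sim N(0,1)$. The
proposal is compared against a randomly chosen nest and replaces it if
better; then each non-elite nest is abandoned with probability `pa_abandon`
and rebuilt by a biased random walk along the difference of two randomly
permuted population members. The best nest is exempt from abandonment and
the global best is updated against every single evaluation, so the
best-so-far trace is monotone. Fitness comparison is lexicographic: higher
cross-validated rate first, fewer support vectors on exact rate ties, the
incumbent on full ties — on a landscape whose rate plateaus at 100%, the
optimiser therefore keeps strictly reducing model complexity.

Defaults (25 nests, `pa_abandon` 0.25, $\alpha = 1.5$, step scale 0.01, 50
iterations, one egg per cuckoo per iteration) follow the canonical Cuckoo
Search description. Numerical notes, found the hard way:

* The Mantegna constant $\sigma_u(\alpha)$ contains $\sin(\pi\alpha/2)$ and
  therefore vanishes at $\alpha = 2$: at the Gaussian end of the family the
  steps degenerate to zero rather than to a Gaussian. Keep $\alpha$
  strictly below 2 (the default 1.5 is standard); the simplified Mantegna
  body is also not Gaussian for any $\alpha$, only its tail index matters.
* The $(x - x_{\mathrm{best}})$ factor is the only step-size contraction
  mechanism, so terminal convergence is seed-dependent: the prescribed 2-D
  sphere benchmark (15 nests, 200 iterations) reaches $10^{-3}$ or far
  better on typical seeds but can stall at $10^{-1}$ on unlucky ones. For
  SVM model selection this is irrelevant — the fitness landscape has broad
  plateaus and the tie-break, not terminal refinement, does the work — but
  the optimizer should not be used as a general-purpose fine-precision
  minimiser.
* The cross-validation fitness redraws its fold assignment on every
  evaluation, so fitness is mildly stochastic. This mirrors an experimental
  procedure in which every evaluation retrains on a freshly chosen inner
  split, and it prevents the optimiser from overfitting one particular fold
  layout.

## The experiment harness

`run_baseline_grid()` reproduces the classical benchmark layout: feature
sets {MAV}, {WL}, {MAV, WL, WAMP}, {MAV, WL, SSC} crossed with the three
kernels at default parameters ($\gamma = 1/d$, $c_0 = 1$ for the polynomial
families, $C = 1$, degree 3 — the values a practitioner would reach for
absent other guidance), each cell averaged over repeated stratified 50/50 train/test splits
(10 repeats by default; the split fraction and repeat count are knobs, as
the original procedure reports neither). `run_cs_experiment()` runs the
optimised classifier on the *same* per-repeat splits (both draw their split
from the seed `rng_seed + repeat`), so optimised-versus-baseline
comparisons are paired. Reported per row: the six per-gesture rates, their
arithmetic mean, the standard deviation of the repeat means, the mean
multiclass rate, and the mean support-vector count per class.

## What the synthetic generator emulates — and what it does not

No public recordings exist for this six-gesture, two-channel, 16 Hz
setting, so `generate_recording()` synthesises sessions with the same
structure: per gesture, twenty repetitions of rest (2 s) → sudden onset
(1-sample step, jittered ±62.5 ms) → 5 s hold → rest. A 16 Hz stream from
a two-channel clinical device is necessarily a processed, rectified
envelope — raw EMG at 16 Hz would be meaningless — so the signal model is a
nonnegative activation envelope plus half-normal noise (`|N(0, σ²)|`),
with σ = 1 in arbitrary device units.

Mean activation levels come from a physiologically motivated 6 × 2
template: HC and WF flexor-dominant, HO and WE extensor-dominant, IF and T
low-amplitude mixed patterns that are deliberately the closest pair, so the
finger gestures remain the hardest classes — a qualitative emulation of how
such data behaves, never a quantitative one. The template is scaled so that
the minimum pairwise distance between gesture rows equals
`class_separation × noise_sd`; the default separation of 6 makes the
classes well separated but not trivially so at the window level.

What this means for interpreting results: on synthetic sessions the
pipeline reaches ~100% accuracy and the optimised classifier matches or
beats every fixed-kernel baseline while using far fewer support vectors.
Those are *correctness* properties of the machinery (and they do reproduce
the qualitative ordering reported for the original recordings: optimised ≥
fixed kernels, MAV the best single feature, finger gestures hardest,
support-vector counts collapsing after optimisation). They say nothing
quantitative about real forearm SEMG, whose amplitude statistics,
inter-repetition variability, electrode shifts and fatigue drifts the
generator does not model. Published accuracies from the original study
(mean rates near 98% optimised, 85–97% for fixed kernels) cannot be
reproduced without the original, undeposited recordings and are not
asserted anywhere in this package's tests.

## Degenerate inputs and tie-breaks, in one place

* Windows shorter than 3 samples are a configuration error (SSC needs an
  interior point); a recording shorter than one window segments to an empty
  list.
* Windows straddling annotation boundaries: majority labelling, with
  gesture beating REST on ties and the earlier-starting annotation winning
  gesture–gesture ties; a `strict` policy drops mixed windows instead.
* REST windows are excluded from classifier training by default — the
  classifier's job is the six gestures.
* Zero-variance feature dimensions pass through the normalizer unchanged.
* Prediction ties take the first class in label order; optimiser full ties
  keep the incumbent; stratified splits and folds differ by at most one
  sample per class.

## Problem sizes used in the shipped checks

The package's own test suite and the acceptance script run entirely on
synthetic data at the study's native scale (a full session is 6 × 20
repetitions ≈ 3,200 gesture windows) for the end-to-end checks, with
smaller sessions (2–3 repetitions) for unit-level properties, and a
deliberately small optimisation budget (5–6 nests, 5–6 iterations) for the
model-selection experiments — on these landscapes the rate plateau is
reached within a handful of iterations, and the small budget keeps the
whole suite comfortably reproducible on a laptop.
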
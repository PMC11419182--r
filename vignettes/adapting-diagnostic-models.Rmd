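---
title: "Adapting diagnostic models across population groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adapting diagnostic models across population groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortadapt)
```

## The problem

A diagnostic model trained on one population stratum (a study, a sex, an age
band, a race group) meets two kinds of shift when deployed on another:
*covariate shift* (the feature distribution moves) and *concept shift* (the
feature–label relationship moves). With a large labelled sample from the new
population one would simply retrain; with none one must hope the source model
transfers. The interesting regime is in between: a handful of labelled
target samples that is too small to train on but too informative to discard.

`cohortadapt` treats that regime with one scalar knob. Given $m$ source
samples and $n$ target samples, the $\alpha$-weighted empirical risk is

$$\hat R_\alpha(\theta) \;=\;
  -\frac{1-\alpha}{m}\sum_{i \in \text{source}} \log p_\theta(y_i \mid x_i)
  \;-\;\frac{\alpha}{n}\sum_{i \in \text{target}} \log p_\theta(y_i \mid x_i).$$

Because the objective is a weighted likelihood, it is realized for *any*
weight-accepting learner by per-sample weights $(1-\alpha)/m$ and
$\alpha/n$ (`erm_weights()`), which always sum to one. Three identities pin
down the implementation and are asserted exactly in the test suite:
$\alpha = 0$ is the source-only fit, $\alpha = 1$ the target-only fit, and
$\alpha = n/(m+n)$ gives every sample equal weight — pooled training. For
convex learners the weighted fit coincides with training on a dataset in
which samples are replicated proportionally to their weights; the tests
verify logistic coefficients against that replicated-dataset oracle to
1e-6.

$\alpha$ is selected on the grid $k/(k+1)$, $k = 1,\dots,10$ — denser near 1
where the objective is most sensitive when $n \ll m$ — by inner
cross-validation (`select_alpha()`): for each candidate, weighted fits on
fold complements predict their validation folds, and the score is the metric
on the pooled target-role validation predictions. Ties break toward the
smallest $\alpha$ (prefer more source data). $\alpha = 0$ is always
evaluated as the explicit baseline but never selected; reporting it makes
"adaptation did not help here" visible rather than silent.

## Quantifying the shift

How far apart two groups are is measured by the squared maximum mean
discrepancy. The unbiased U-statistic estimator on equal samples of size
$n$ is

$$\widehat{\mathrm{MMD}}^2_u = \frac{1}{n^2 - n}\sum_{i \ne j}
  \bigl[k(x_i, x_j) + k(x_i', x_j') - k(x_i, x_j') - k(x_i', x_j)\bigr],$$

which can be negative near the null — a property the tests assert rather
than suppress. Significance comes from a permutation test with the add-one
p-value $(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$, so the smallest
attainable p-value is $1/(B+1)$ and the test is exact at any level that is a
multiple of $1/(B+1)$. One pooled Gram matrix is computed once and re-indexed
for all permutations.

The default kernel is linear *on an embedding*: `train_feature_map()` fits a
single multi-layer perceptron with a shared trunk (three ReLU layers,
default 64–48–32) and one softmax head per demographic attribute, trained
jointly with full-batch Adam so that all attributes share one feature space
and their MMD values are comparable. The trunk's last hidden layer is the
embedding; a linear kernel on it is exactly the inner product of that
learned feature map. `pairwise_shift()` assembles the pairwise MMD² matrix,
permutation p-values, and an average-linkage dendrogram (distances clamp
negative estimates to zero; statistics are never clamped). Unequal groups
are subsampled to the smaller size with a recorded seed.

## Theory-side guidance and its limits

The excess target risk of the $\alpha$-weighted minimizer is bounded (up to
the best-in-class risk) by

$$g(\alpha) = 4\sqrt{\Bigl(\frac{\alpha^2}{n} + \frac{(1-\alpha)^2}{m}\Bigr)
  (V - \log\delta)} + 2(1-\alpha)\,d,$$

with capacity proxy $V$, confidence $\delta$ and source–target discrepancy
$d$. `optimal_alpha()` honors two closed forms exactly — $d = 0$ gives
$\alpha^* = n/(m+n)$, and $n \ge 4(V-\log\delta)/d^2$ forces $\alpha^* = 1$
(the derivative at 1 is $4\sqrt{(V - \log\delta)/n} - 2d \le 0$ and $g$ is
convex) — and minimizes numerically in between. Both $V$ and $d$ are hard to
estimate in practice ($\sqrt{\max(\mathrm{MMD}^2,0)}$ is offered as a crude
plug-in); the bound is orientation, and cross-validation remains the
operational selector. The package keeps the exact arithmetic and the
heuristic plug-ins clearly separated.

```{r bound, fig.width = 6, fig.height = 4}
autoplot(bound_params(m = 1000, n = 100, V = 1, delta = 0.05, d = 0.25))
```

## The synthetic cohort generator

Real consortium tables are restricted, so every stage is exercised on
synthetic cohorts (`cohort_spec()` / `generate_cohort()`):

- numeric features are equicorrelated Gaussians (optionally log-normal
  columns), with per-group mean shifts in SD units and per-group covariance
  scaling;
- labels come from per-group logistic (or linear) models, so covariate and
  concept shift are controlled independently; `class_balance` tunes the
  intercept by root-finding to hit a marginal positive rate;
- `inject_missingness()` masks feature columns completely at random at
  per-column rates, emulating sparsely observed clinical columns; labels and
  group assignments are never masked;
- `make_progression_labels()` assigns pMCI/sMCI/nMCI from a latent severity
  score: with standardized severity $s$ and independent $e \sim N(0,1)$,
  $v = \Phi\!\bigl((\lambda s + e)/\sqrt{\lambda^2+1}\bigr)$ is uniform
  marginally, so quantile cuts reproduce the class priors while higher
  severity monotonically favors progression.

What the generator does *not* emulate: longitudinal follow-up (progression
is a cross-sectional stand-in), site/scanner batch effects, informative
missingness, measurement error correlated with the label, and realistic
feature counts (20 numeric features by default, not hundreds of ROI
volumes). Conclusions about *mechanisms* transfer; absolute metric values do
not.

The packaged benchmark condition (`example_adaptation_spec()`) fixes a
moderate compound shift once: $m = 1000$, $n = 200$, a $+0.5$ SD mean shift
on the five label-active features, and a sign flip of two of the five label
coefficients in the target group. Covariate shift alone would leave a
logistic source model near-optimal on the target; the compound shift is the
regime where a few target labels genuinely matter. On this condition the
weighted model beats the source-only baseline in roughly 95% of seeded
replicates (`adaptation_gain_experiment()`).

## Protocol hygiene

`make_split_plan()` builds the outer five-fold geometry for three settings:
`"0%"` (train on source, test on the whole target group), `"10%"` (train on
source plus $\lfloor 0.1 n\rfloor$ stratified target rows from fold $f$,
test on the target rows outside fold $f$), and `"all"` (source plus 80% of
target, test on the held-out 20%). Fold assignment is stratified by label
with the dealing pointer carried across strata, so fold totals differ by at
most one and the 10% counts are exactly
$\lfloor 0.1n\rfloor / \lfloor 0.8n\rfloor / \text{remainder}$.

`evaluate_adaptation()` refits the preprocessor *inside* each fold on
training rows only. The preprocessing state — median imputation constants,
population-variance ($\div n$) standardization, rank-based quantile maps to
$\Phi^{-1}$ scores for columns with |skewness| > 1, categorical
vocabularies with an `"(unknown)"` category absorbing both missing and
unseen values, and missingness-indicator bookkeeping — is a pure function of
the training rows; the tests certify this with a mutation test that perturbs
test rows and asserts bit-identical fitted state. A practical note on the
skewness gate: the maximum possible |skewness| of three points is
$\approx 0.707$, so tiny columns never trip the default threshold of 1; the
threshold is a parameter for callers who want the quantile map regardless.

## Ensembling and downstream analyses

`fit_ensemble()` is a two-level stack: each base learner (logistic, k-NN,
random forest, gradient-boosted trees, MLP) produces out-of-fold predictions
under repeated stratified k-fold bagging — every row predicted only by
models that never saw it — and the stacking layer trains on those OOF
columns concatenated with the original features. Greedy ensemble selection
with replacement over the stack models' own OOF predictions yields blend
weights whose validation loss provably never exceeds the best single model.
All fits accept the $\alpha$ weights, so `ensemble_learner()` drops the
whole stack under `adapt()`.

Two clinical procedures consume trained models. `lda_progression()` runs a
one-dimensional two-class LDA (pooled variance, empirical priors) on the
disease probability assigned to MCI subjects, trained on one fold (20% of
labels) and evaluated by AUC on the rest, per class pair. With equal priors
the decision boundary is exactly the midpoint of the class means.
`brain_age_residuals()` computes predicted minus chronological age and
`bar_correlations()` its Pearson correlations with clinical variables (exact
t-test p-values); cognitive scores that decline with aging should correlate
negatively, timed tests that slow down positively.

## Numerical and reproducibility choices

- All randomness flows through integer seeds; internal routines save and
  restore the caller's RNG state, and derived seeds use a fixed
  congruential map (`(seed \cdot 48271 + k \cdot 16807) \bmod 2147483629`),
  keeping every seed below $2^{31}$.
- AUC is the rank (Mann–Whitney) form with ties counting one half; the tests
  check it against exhaustive pair enumeration. Fold summaries report the sd
  of the fold metrics, not a pooled recomputation.
- JSON serializers write 17 significant digits, the minimum that
  round-trips IEEE doubles exactly.
- Calibration experiments derive the permutation seed from the data seed
  through the congruential map rather than reusing it: re-using one integer
  for both streams measurably biases the estimated type-I error.

Problem sizes used throughout the tests (cohorts of 30–4000 rows, 8–25
features, permutation counts 19–999, 20–500 replicates) are chosen so the
full suite runs in about three minutes on one core while keeping binomial /
Monte-Carlo confidence intervals tight enough to be meaningful.
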
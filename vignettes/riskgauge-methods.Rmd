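---
title: "Measuring risk-model performance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring risk-model performance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskgauge)
```

## The measures

Take a sample of $N$ subjects with binary disease indicators
$D_i \in \{0,1\}$ ($N_1$ diseased, $N_0 = N - N_1$ non-diseased) and a
model assigning each subject a predicted probability $p_i \in [0,1]$.
Write $\bar p$ for the reference (a priori) probability. Before any model
is applied, every subject carries the same probability $\bar p$; a useful
model spreads subjects away from it. The package quantifies that spread
in four ways.

**AUC.** The probability that a randomly chosen diseased subject receives
a higher predicted probability than a randomly chosen non-diseased one,
with tied pairs scoring $1/2$:
$$\mathrm{AUC} = \frac{1}{N_1 N_0} \sum_{i: D_i = 1}\,\sum_{j: D_j = 0}
  \Big[\mathbb{1}(p_i > p_j) + \tfrac12 \mathbb{1}(p_i = p_j)\Big].$$
`auc()` computes this with midranks in $O(N\log N)$, which equals the
pairwise definition exactly (the test suite asserts the equality against
a brute-force loop and against `pROC`). `roc_points()` builds the
empirical ROC curve, and the trapezoidal `roc_area()` agrees with the
pairwise form to machine precision, tied values included.

**Gini.** The mean absolute pairwise difference of predicted
probabilities — a measure of *separation* between subjects — divided by
its value under the error-free model ($p_i = D_i$), so that 1 means "as
much separation as a perfect model could induce":
$$\mathrm{Gini} = \frac{\sum_i \sum_j |p_i - p_j|}{2 N^2\, \bar p (1-\bar p)}.$$

**Pietra.** The mean absolute deviation from the prior — the *gain* a
subject can expect in moving from the a priori to the a posteriori
probability — standardized the same way:
$$\mathrm{Pietra} = \frac{\sum_i |p_i - \bar p|}{2 N\, \bar p (1-\bar p)}.$$

Both have Lorenz-curve readings, implemented in `lorenz_points()`,
`gini_from_lorenz()` and `pietra_from_lorenz()`: sort subjects by
ascending $p$ and plot cumulative risk share against cumulative
population share. The classical Lorenz Gini (twice the area between the
diagonal and the curve) divided by $1-\bar p$ is the standardized Gini;
the maximum vertical deviation of the curve from the diagonal divided by
$1-\bar p$ is the Pietra. The formula and geometric routes agree to
$10^{-9}$ on randomized instances in the tests; the maximum deviation is
taken exactly over the curve's vertices (it is piecewise linear, so no
grid search is involved), and tied $p$ values are grouped into a single
segment so ties cannot create artificial vertices.

**Scaled Brier.** The Brier score $N^{-1}\sum_i (D_i - p_i)^2$ depends on
prevalence, so the package reports
$$\mathrm{sBrier} = 1 - \frac{\mathrm{Brier}}{\bar p(1-\bar p)},$$
the improvement over the constant-prior predictor: 1 for the error-free
model, 0 for the constant predictor, negative for a model that predicts
worse than the prior. A negative value is returned with a warning rather
than clamped — it is a diagnostic of miscalibration, not an artifact.
`scaled_brier_gain()` is the probability-only companion
$\sum_i (p_i-\bar p)^2 / (N \bar p (1-\bar p))$; the two coincide for
predictions that are perfectly calibrated in-sample.

**Identities.** For in-sample-calibrated predictions (the mean outcome at
every distinct predicted value equals that value) two exact identities
hold, and the test suite verifies both to $10^{-9}$ on algebraically
constructed samples: $\mathrm{Gini} = 2\,\mathrm{AUC} - 1$, and the
change in sBrier between two calibrated models equals the IDI. Fitted
logistic models on validation data satisfy both only approximately; the
tests check them there within Monte-Carlo error (3 standard errors over
200 replicates). These identities are the reason the Gini improvement
from adding a marker is always about twice the AUC improvement, and why
the IDI — a relative measure — can be read off the absolute sBrier.

### The reference probability

All three standardized indices need $\bar p$. The default is the observed
prevalence $N_1/N$; `reference = "mean_predicted"` substitutes the mean
predicted probability. For a model calibrated in the large the two
coincide; they differ on miscalibrated validation samples. Observed
prevalence is the default because it keeps the constant-prior predictor's
sBrier at exactly 0 regardless of the model's calibration. The Lorenz
curve, built from the probabilities alone, always uses the mean predicted
probability, which is why the geometric-equivalence tests set
`reference = "mean_predicted"`.

## Relative measures and the transitivity audit

`nri()` (category-based), `cnri()` (any probability movement counts;
exact ties are no movement — an exact equality test, deliberately without
tolerance, so behavior is deterministic) and `idi()` (change in
discrimination slope) compare an old and a new model on the same
subjects. NRI is returned as a single number, with the event/non-event
components available via `components = TRUE`.

Pairwise preference by NRI is not transitive: it is a majority-style
aggregation of per-subject movements, and like any such rule it can
produce Condorcet cycles. `transitivity_audit()` computes the full
pairwise NRI/cNRI matrices for three or more models and reports every
cyclic triple; `find_nri_cycle()` searches randomized small cohorts
(jittered versions of a common risk signal, 20 subjects, tertile-style
cuts) until it finds one, which it reliably does within a few hundred
attempts. No search is needed on the absolute side: an index that attaches
one real number to each model induces a total order, so AUC, Gini, Pietra
and sBrier can never cycle — the audit recomputes them on the found triple
to make the contrast concrete.

## The data-generating model

`simulate_cohort()` draws, per subject,

* a baseline score $B \sim N(0,1)$ — standing in for a standardized
  composite of traditional risk factors;
* binary markers $M_1, M_2$ with $P(M = 1 \mid B > 0) = 0.85$ and
  $P(M = 1 \mid B \le 0) = 0.75$, conditionally independent given $B$ —
  a simple device that correlates each marker with the baseline score
  while keeping its marginal prevalence at 80%;
* the disease outcome from
  $$\mathrm{logit}\,P(D=1) = \alpha + \beta_B B + \gamma_1 M_1 +
    \gamma_2 K(B)\, M_2, \qquad K(B) = e^{-B^2 / 2w^2}.$$

$M_1$'s odds ratio $e^{\gamma_1}$ is constant in $B$. $M_2$'s conditional
odds ratio $e^{\gamma_2 K(B)}$ peaks at $B = 0$ — precisely the *gray
zone*, where the baseline model's predicted probability sits near the
prior and the model is uninformative — and decays to 1 for $|B| \gtrsim
3w$. $M_2$ is therefore a gray-zone resolving marker: it is strongly
informative exactly for the subjects the baseline model cannot place.

### Default parameters and how they were fixed

The defaults of `generating_params()` define the package's reference
study conditions, chosen once and frozen:

| parameter | default | meaning |
|---|---|---|
| `intercept` ($\alpha$) | −2.55 | prevalence ≈ 0.48 |
| `beta_baseline` ($\beta_B$) | 1.73 | OR ≈ 5.6 per SD of $B$; baseline-model AUC ≈ 0.82 |
| `log_or_m1` ($\gamma_1$) | 1.52 | OR ≈ 4.6, uniform in $B$ |
| `log_or_m2_peak` ($\gamma_2$) | 2.05 | peak OR ≈ 7.8 at $B = 0$ |
| `kernel_width` ($w$) | 0.75 | SD units of $B$; OR ≈ 1 beyond $|B| \approx 2.3$ |
| `marker_prev_high` / `_low` | 0.85 / 0.75 | marker prevalence given $B > 0$ / $B \le 0$ |

The four effect parameters were calibrated jointly so that the reference
experiment (below) lands at a baseline-model validation AUC near 0.822
with Gini/Pietra/sBrier near 0.644/0.485/0.306, an AUC gain of about
+0.019 when $M_1$ is added, and a Pietra gain of about +0.083 when $M_2$
is added — the canonical situation the package is built to study: a
strong uniform marker that the AUC barely credits, and a gray-zone
marker that the gain-type indices value far more highly than the
separation-type ones. Calibration used replicate experiments at the
reference cohort sizes and was done once; the values are frozen and the
remaining cells of the experiment table (the $B{+}M_1$ sBrier gain, the
$B{+}M_2$ AUC/Pietra levels) follow from them rather than being targeted.
One structural note: within this generator family the ratio of the
$M_2$ sBrier gain to its Pietra gain stays near 0.8; $\gamma_2$ was set
at the value balancing the two cells rather than matching either one
alone. `solve_intercept()` re-solves $\alpha$ for any requested
prevalence by root-finding on the simulated mean of $p_{\mathrm{true}}$
with covariate draws held fixed, so users can move the prevalence without
disturbing the effect structure.

Because $p_{\mathrm{true}}$ comes from the generating model itself, it is
perfectly calibrated by construction (binned subjects' mean outcome
matches the bin's mean $p_{\mathrm{true}}$ within Monte-Carlo error) —
this is the regime in which the algebraic identities above hold, and the
property tests for the other modules use it as their harness.

### Supplementary scenarios

`simulate_cohort_continuous()` swaps the binary markers for one
continuous marker, standard normal with a configurable mean shift when
$B > 0$, entering the model linearly or (with `kernel_effect = TRUE`)
through the kernel-modulated coefficient. `simulate_cohort_polygenic()`
generates $k$ mutually independent weak binary markers (default:
$k = 18$, per-marker OR 1.2, carrier frequency 0.3 — chosen as a
realistic genetic-score setting in which each variant is individually
near-useless) and their unweighted sum as a `score` column; the fitted
score model's AUC gain exceeds any single marker's gain in the large
majority of replicates, the collective-strength phenomenon the scenario
exists to show.

## The replicate experiment

`run_experiment()` executes the design described by
`experiment_config()`: per replicate, simulate a training and a
validation cohort (defaults 500 + 500 subjects), fit the three logistic
models — baseline `B`, `B+M1`, and `B+M2` — on the training cohort, and
evaluate AUC, Gini, Pietra, Brier and sBrier on the validation cohort.
Choices worth knowing:

* **Evaluation sample.** Validation by default, to keep the measures free
  of resubstitution optimism; `evaluate_on = "training"` is available for
  sensitivity checks.
* **Form of the M2 model.** `m2_form = "kernel"` (default) fits
  $\mathrm{logit}\,P(D=1) = a + b B + c\, K(B) M_2$, i.e. the analyst
  knows the marker is gray-zone structured; `"main"` fits $M_2$ as a
  plain main effect. The main-effects fit averages the kernel profile
  over $B$ and behaves like a weak uniform marker (Pietra gain around
  +0.04 rather than +0.08 under the defaults), erasing the gray-zone
  depletion that `probability_histograms()` makes visible; the kernel
  form is the default because the experiment exists to study that
  depletion.
* **Seeding.** Replicate $r$ re-seeds the RNG at `base_seed + r` and
  draws the training then the validation cohort from that stream, so any
  replicate can be reproduced in isolation and results are bit-identical
  across runs of the same configuration.
* **Degenerate replicates.** A single-class cohort, a non-converged fit
  (IRLS relative-deviance tolerance $10^{-8}$, 100 iterations) or
  (quasi-)separation raises an internal `riskgauge_skip` condition; the
  replicate is dropped and counted in `n_skipped` with its reason
  recorded, never imputed. Under the default parameters at $n = 500$
  skips are essentially absent; they matter for small-cohort
  explorations.
* **Aggregation.** Arithmetic means over retained replicates, with
  Monte-Carlo standard errors for every cell. Improvements are reported
  both as means of per-replicate deltas and as deltas of the aggregate
  means (equal up to floating point — asserted in the tests); relative
  improvements are percentages of the baseline aggregate.

The package's reference experiment — also what `scripts/acceptance.R`
runs — uses 1000 replicates, which puts Monte-Carlo standard errors on
the aggregate measures near 0.001 and runs in a few minutes on one CPU;
the experiment scales to more replicates by raising `n_replicates`.

`probability_histograms()` (on a `run_experiment(...,
keep_predictions = TRUE)` result) bins the pooled validation predictions
by model and disease status around the grand and class-specific means.
Under the defaults the $B{+}M_2$ model's histogram mass near the grand
mean is visibly depleted relative to the baseline model: the gray zone
empties, diseased subjects move right, non-diseased move left. That — and
not a large ROC-area movement — is the signature of a gray-zone resolving
marker, and it is why Pietra and sBrier, which measure deviation from the
prior, respond to $M_2$ while AUC and Gini barely do.

## Numerical choices

* The Gini double sum uses the sorted identity
  $\sum_i\sum_j |p_i - p_j| = 2\sum_k (2k - N - 1)\, p_{(k)}$
  ($O(N\log N)$), tested exactly against the naive $O(N^2)$ loop up to
  $N = 200$ (`gini_index(naive = TRUE)`).
* `predict_risk()` clips fitted probabilities to the open interval
  $(\epsilon, 1-\epsilon)$ at machine epsilon, honoring the contract that
  predictions are strictly inside $(0,1)$ even for extreme covariates.
* Degenerate inputs (single-class samples, $\bar p \in \{0,1\}$, zero
  total risk) raise informative errors rather than returning `NaN`, so
  replicate loops can count and skip them.
* NRI category assignment uses right-open intervals
  (`findInterval`): a probability exactly at a cutpoint belongs to the
  higher category; the same rule is applied to both models, so the
  convention cannot bias the up/down contrast.

## What the simulation does and does not show

The generator produces idealized cohorts: covariates are exactly normal
or Bernoulli, the disease model is exactly logistic, markers are
conditionally independent given $B$, there is no measurement error, no
missingness, and outcomes are instantaneous (no censoring or follow-up
time). Passing the package's tests therefore shows that the measures and
the experiment machinery behave correctly under the stated model — it
does not show that any particular marker in real data is gray-zone
resolving, nor that the specific improvement magnitudes transfer to real
cohorts, where miscalibration, case-mix differences and model
misspecification all move the indices. Statistical inference for the
indices (confidence intervals, hypothesis tests) is out of scope;
everything here is a point estimate with, where replicated, a
Monte-Carlo standard error.
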
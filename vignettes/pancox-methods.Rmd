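---
title: "Methods: pan-cancer prognostic modeling on left-truncated clinico-genomic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-cancer prognostic modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Prognostic overall-survival models in oncology are usually built per cancer
type, on whatever cohort is available. Clinico-genomic registries that pool
many cancer types raise a transfer-learning question: does a single
*pan-cancer* model — trained on pooled data with cancer-type covariates —
beat models trained separately per cancer, especially for the small cohorts?
`pancox` implements the full experimental loop needed to study that question
on synthetic data: cohort simulation, feature engineering from lab time
series and panel genomics, imputation, a penalized Cox solver that handles
the registry's delayed-entry structure, evaluation, and the pan-vs-single
comparison harness.

A registry built around genomic testing only observes a patient once they
are tested. With survival measured from first-line therapy start (day 0),
a patient who dies before testing never enters the database: survival times
are *left-truncated* at the entry time (therapy start to test). Ignoring
this biases every downstream estimate toward long survivors.

# The model

The core model is a lasso-penalized Cox proportional-hazards regression.
For subject $i$ with entry time $e_i$, exit time $t_i$ and event indicator
$\delta_i$, the risk set at time $t$ is $R(t) = \{j : e_j < t \le t_j\}$
(the risk-set adjustment for left truncation). With Breslow tie handling,
the solver minimizes

$$-\tfrac{1}{n}\,\ell(\beta) + \lambda \sum_j w_j |\beta_j|,$$

where $\ell$ is the partial log-likelihood over those risk sets and $w_j$
are penalty factors; the entry-time covariate and the cancer-type
indicators default to $w_j = 0$ ("adjusted for", not penalized). The entry
time also enters as a covariate, targeting quasi-independence between entry
and survival.

## Optimization and certification

The solver is an iteratively reweighted least squares scheme with cyclic
coordinate descent (`src/coxlasso.cpp`): at each outer iteration, the
gradient and the exact diagonal of the Hessian of $\ell$ with respect to
the linear predictor define a weighted least-squares subproblem, solved by
coordinate descent with an active-set strategy. Two numerical details
matter:

* The diagonal working Hessian over-estimates curvature (the neglected
  off-diagonal risk-set terms are negative semi-definite in aggregate), so
  the IRLS step is conservative. After each inner solve the solver tries
  doubling the step and keeps whichever iterate has the lower penalized
  objective. This roughly halves the outer-iteration count.
* Convergence is declared per path point only when a Karush–Kuhn–Tucker
  check on the *exact* partial-likelihood gradient passes (default
  tolerance `5e-7`, well inside the 1e-6 certificate asserted in the test
  suite); coordinate updates stop at `1e-7` on the standardized scale. The
  exported `kkt_certificate()` recomputes the violation from the data.

The $\lambda$ path has 100 log-spaced points from $\lambda_{\max}$ (the
largest gradient component over penalized features after fitting the
unpenalized covariates alone) down to $0.01\,\lambda_{\max}$. Automatic
paths stop early when the deviance ratio saturates (≥ 0.99 of the
saturated Breslow deviance) or stops improving — the standard device that
keeps the dense tail of the path tractable. Features are standardized
internally; coefficients are reported on the original scale.

$\lambda$ is selected by 5-fold cross-validation maximizing the held-out
concordance index, folds stratified by cancer type and event status,
scores computed within each fold and averaged, ties resolved toward the
larger $\lambda$. Survival curves come from a Breslow baseline cumulative
hazard with the same left-truncated risk sets.

# Feature engineering

Laboratory series are summarized in two windows before the index date, 60
and 720 days (half-open, `[-W, 0)`, so same-day labs cannot leak outcome
information). Values are first mapped to the normal range by
$(v - \mathrm{LLN}) / (\mathrm{ULN} - \mathrm{LLN})$ — a min–max convention
chosen because the upstream description ("normalized to their upper and
lower limits of normal") does not pin a formula; 0 and 1 then correspond
to the normal-range bounds. Eleven summaries are emitted per (analyte,
window): mean, median, variance, max, min, approximate entropy,
difference and slope of the last two values, test count, count over the
available window (denominator `min(window, observed record length)` — an
interpretive choice, flagged), and the proportion of abnormal values
(strictly outside the limits; the limits themselves count as normal).
Single-observation windows leave variance/difference/slope missing rather
than zero — "no information" is not "no variability". Approximate entropy
uses the standard Pincus settings $m = 2$, $r = 0.2\,\mathrm{SD}$
(self-matches included), since the source does not state them.

Genomics are encoded as one binary column per (gene, variant class) with
unmeasured panel entries kept missing for the kNN imputer, pathway
impacted/not flags (impacted iff any member gene carries any reported
alteration), and the componentwise mean of the embedding vectors of the
affected genes (zero vector when none).

Screening removes zero-variance features, dummies with fewer than 20
positive training counts, and features missing in over 30% of the training
cohort. One-hot encoding drops the training-majority level; continuous
features are z-scored with training statistics and clipped at ±3. Binary
columns stay on the 0/1 scale (the clipping rule names z-scores, the
count rule names dummies). Cancer-specific features are set to 0 outside
their cohort — structured missingness is design, not information — before
normalization statistics are computed on in-scope training rows. Every
fitted statistic is a pure function of training rows; a property test
corrupts all test rows and asserts the statistics do not move.

# Imputation

Genomic binaries use k-nearest neighbours (default $k = 5$): Euclidean
distance over co-observed features scaled by their number, unweighted mean
of the $k$ nearest donors, binary results rounded at 0.5 with ties to 0.
Donor rows are training rows plus an optional external reference table
(emulating public-cohort augmentation). Clinical features use chained
equations with predictive-mean matching (donor pool 5, 10 sweeps, at most
15 predictors per model chosen once by correlation — a tractability bound)
and logistic draws for binaries. `m` completed datasets are supported;
the pipeline consumes the first, matching the upstream report that results
were similar across imputations.

# Evaluation

* **Concordance**: ordered pair $(i, j)$ comparable iff $\delta_i = 1$ and
  $e_j < t_i < t_j$ — subject $j$ must already be under observation when
  $i$ dies. Ties in scores count one half.
* **Integrated Brier score**: inverse-probability-of-censoring weights from
  a left-truncation-adjusted Kaplan–Meier of the censoring distribution
  fitted on training data, weights capped at 20; the Brier curve is
  averaged (trapezoid) between the first test event and the 95th
  percentile of test exit times. Both the horizon and the cap are
  implementation choices; the source is silent.
* **Risk stratification**: groups split at the per-cohort training median
  of the risk score $\exp(\hat\eta)$; the hazard ratio is reported as
  hazard(low)/hazard(high) from a one-covariate unpenalized left-truncated
  Cox model with a Wald 95% CI, matching the direction of the published
  values (< 1 for prognostic scores).
* **Uncertainty**: bias-corrected bootstrap percentile intervals
  ($z_0$ correction, acceleration 0), resampling train and test rows with
  replacement, stratified by cancer type. The comparison harness offers a
  fast mode (score-only test resampling) and a refit mode (refit at the
  selected $\lambda$ per replicate, preprocessing reused). A full
  pipeline refit including imputation and CV per replicate is faithful to
  the source description but is far outside a desk-scale budget at
  B = 1000; the fast mode is the harness default, and a directional test
  asserts fast intervals are not wider than refit intervals.

# The synthetic world

The generator emulates the statistical structure the analysis assumes, not
any particular biology: K cancer cohorts of heterogeneous size; Weibull
baseline hazards per cancer (shape 1.1, scales 300–900 days, spanning
median survivals of roughly one to three years); a linear predictor built
from shared covariates (standardized age, ECOG, sex first, then generic
clinical risk factors), cancer-specific covariates observed only in their
cohort, and optional gene-variant effects; exponential entry times
(default mean 60 days) creating a controllable truncation fraction;
independent exponential censoring plus an administrative horizon (10
years); lab values whose analyte-specific means drift with the subject's
true risk (so window summaries become prognostic without dictating a
mechanism); gene-variant prevalences interpolated per cancer; ~5% of
panel calls unmeasured; day-resolution times with ties. Cohort sizes are
post-truncation targets achieved by oversampling, keeping per-cancer n
exact for experiment design. Embeddings are fixed random unit vectors —
only the averaging operation is under test.

## The transfer-contrast world

The pan-vs-single acceptance world deserves its own account, because the
transfer advantage is a *regime*, not a universal. Two findings from
designing it:

* With strong sparse signal (a handful of |log-HR| ≈ 0.3–0.45 effects), a
  120-subject cohort recovers the signal on its own and pan training adds
  nothing. The advantage appears in the low-information regime the
  upstream study describes: many weak effects (here 100 shared effects of
  |log-HR| = 0.08 among 200 candidates) and event-poor small cohorts
  (~50% censoring, ≈ 55 training events in the smallest cohort).
* Lab summaries must be absent from that world. The generator links every
  analyte's mean to the subject's entire linear predictor, so one lab
  column is an aggregate readout of the whole signal (correlation ≈ 0.7)
  — with it, even the smallest cohort reads the risk off a single feature
  and the single-cancer model matches the pan model. Realistic for labs,
  fatal for a diffuse-signal contrast.

In that world the pan model beats the single-cancer model on the smallest
cohort's test set in 17 of 20 seeded replicates, with a mean concordance
gap of about +0.10 (single ≈ 0.53, pan ≈ 0.63); with orthogonal
per-cancer signal and 2,000-subject cohorts the gap vanishes, as it
should.

What a green test does *not* establish: realism of the entry-time
distribution (unknown for the real registry; exposed as config), clinical
plausibility of analyte trajectories, correlated missingness, treatment
effects, or non-proportional hazards. The pan-vs-single contrast is a
qualitative analogue: shared-signal worlds reproduce the small-cohort
transfer advantage, orthogonal-signal worlds erase it.

# Known limitations and open observations

* Under pure noise, the CV curve is flat with ±0.03 fluctuation and its
  argmax is not concentrated near $\lambda_{\max}$; only exact ties favor
  the sparse end. Consequently the "sparser models in smaller cohorts"
  pattern reported upstream does not emerge from max-c-index selection in
  this synthetic world (if anything the opposite, because small-cohort CV
  curves are noisiest). A 1-SE-style selection rule would likely restore
  it, but the source describes plain maximization, so that is what is
  implemented.
* The IBS treats test subjects with entry after the evaluation time as
  standard at-risk observations; with heavy truncation this is biased,
  as it is in common practice.
* The chained-equation imputer bounds each model at 15 predictors; with
  thousands of columns a full MICE pass would dominate the runtime.
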
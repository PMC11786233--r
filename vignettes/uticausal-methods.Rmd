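---
title: "Estimating comparative antibiotic effectiveness from claims: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating comparative antibiotic effectiveness from claims: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

Uncomplicated urinary tract infection (UTI) is one of the most common
outpatient indications for antibiotics. Whether guideline-concordant
first-line agents (nitrofurantoin, trimethoprim-sulfamethoxazole) still
outperform the alternatives — fluoroquinolones and oral β-lactams — is an
inherently observational question at scale: randomization is rare, and in
claims data the sicker, older patients systematically receive the
alternative classes (confounding by indication). A second, subtler problem
is that insurance enrollment ends for reasons correlated with health:
patients who leave the plan before an endpoint's follow-up window closes
are right-censored, and if disenrollment depends on covariates that also
drive the outcome, a complete-case analysis is biased.

`uticausal` implements the full analysis pipeline for this setting over
OMOP-CDM-shaped claims tables: episode-level cohort construction with an
explicit exclusion cascade, two confounder sets (domain-expert and
automatically generated time-windowed covariates), fixed-window binary
endpoint labeling with observation indicators, machine-learned nuisance
models, and a doubly-weighted risk-difference estimator with bootstrap
inference and negative-control diagnostics.

The estimand is the average treatment effect (ATE) on the additive risk
scale for episode $i$ with covariates $X_i$, treatment $T_i$
($T_i = 1$ for first-line), observation indicator $D_i$ ($D_i = 1$ iff the
person remained enrolled for the endpoint's full window) and outcome $Y_i$
(missing when $D_i = 0$):

$$
\widehat{\mathrm{ATE}}
 = \frac{1}{n}\sum_i \frac{T_i D_i Y_i}{e(X_i)\,\pi(X_i)}
 - \frac{1}{n}\sum_i \frac{(1-T_i) D_i Y_i}{(1-e(X_i))\,\pi(X_i)},
$$

the product of inverse probability of treatment weighting through the
propensity $e(X) = P(T=1 \mid X)$ and inverse probability of censoring
weighting through the observation probability
$\pi(X) = P(D=1 \mid X, T)$. This Horvitz–Thompson form and the
weight-normalized Hájek form (each arm divided by its summed weights) are
both provided; **Hájek is the default** because normalization removes the
sensitivity of the unnormalized form to weight-sum fluctuations, at the
price of a small-sample ratio bias that vanishes at the cohort sizes in
scope. With $e \equiv 1/2$, $\pi \equiv 1$, $D \equiv 1$ both forms
collapse to the difference of arm means (the unnormalized form requires
balanced arms for this identity; the Hájek form does not).

Unobserved episodes ($D=0$) contribute zero weight — their $Y$ is missing,
never imputed as zero outcome. Because the observation model conditions on
treatment as well as covariates (the design is $[X, T, T\!\times\!X]$),
censoring is allowed to differ by arm; with arm-independent censoring and
an additive effect, dropping the censoring weights happens to leave the
risk difference almost unbiased, so arm-dependent censoring is exactly the
case the weighting earns its keep on.

## Cohort construction conventions

The source tables give day-resolution events. All window arithmetic is in
days, with **month = 30 days** throughout.

* **Episodes.** Outpatient UTI diagnosis codes are clustered per person;
  diagnoses at most `episode_gap_days` (default 30) apart form one
  episode, indexed at its earliest diagnosis. The gap rule is a
  reproducibility choice: revisits within the follow-up window fold into
  the episode rather than founding new ones.
* **Treatment.** The unique covered antibiotic class dispensed on day
  offsets $[0, 7]$ from the index. The index day sits on the treatment
  side: same-day dispensing is the norm in outpatient UTI care. Washout is
  the preceding $[-7, -1]$: any dispensing there excludes the episode.
  More than one covered class in the window, an off-list antibiotic, or no
  dispensing at all are each exclusion flags.
* **Recurrence.** Counted in sliding windows ending at (and including) the
  index: at least 2 episodes in 180 days *and* at least 3 in 365 days by
  default. The conjunctive reading follows how the definition is usually
  printed; because clinical convention is often disjunctive, the rule is
  configurable (`recurrent_rule = "or"`) and the default announces itself
  with a warning once per cascade.
* **Complicated UTI.** Acute complicating procedures/diagnoses within 180
  days before the index; long-term complicating comorbidities (neurogenic
  bladder, spina bifida, genitourinary cancer) at any prior time; male sex
  always; pregnancy codes within 280 days (gestation-length lookback — the
  population definition says non-pregnant without naming a window).
* **Attrition.** Exclusions are *flags*, never deletions, so eligibility
  is provably independent of rule order; the flow-diagram report applies
  the fixed order male → under-age → pregnancy → washout → recurrent →
  complicated → no-treatment → multi-drug → off-list purely for
  attribution.

## Confounders

Expert features comprise demographics (age, calendar time both raw and in
the three era bins 2012–2014 / 2015–2017 / 2018–2021), chronic-condition
groups and prior antibiotic exposure by class — each binned into the
nonoverlapping history windows (0, 180], (180, 360], (360, 720] days
before the index — plus index-day features: provider specialty one-hots,
urinalysis/blood tests ordered at presentation, a menopause history flag
and a UTI-in-the-past-year flag. History lags are strictly positive, so
nothing on or after the index day can leak into a history window; the
index-day (`at_index`) set is restricted to records dated exactly on the
index. Expert history features are presence indicators: claims codes mark
encounters, not severity, and presence is the robust summary at this
granularity.

Automatic features apply the same windowing to *every* concept code
observed in the conditions, drug and specialty streams — the vocabulary is
derived from the data, which is what lets the mechanism scale from the
package's synthetic vocabulary to a full coding system. A prevalence floor
(default 1%) bounds the dimensionality; at floor zero the automatic
columns over the expert code lists reproduce the expert indicator columns
exactly, which the test suite asserts.

## Nuisance models

Both nuisance models follow one protocol: persons (never episodes) are
split 80/20 into training and test sets, the training set 75/25 into
development and validation subsets; each learner family — regularized
logistic regression, random forest, gradient-boosted trees — tunes its
hyperparameters on development/validation AUROC; families then compete by
person-clustered 3-fold cross-validated AUROC on the training set, and the
winner is refit on the full training set. Person-clustering everywhere
prevents a patient's repeated episodes from straddling a split. Scores are
clipped to $[10^{-4}, 1-10^{-4}]$ before weighting so no single episode
can acquire unbounded weight regardless of trimming; grids ship small
(≤ 6 candidates per family) and are configuration, not claims.

Shapley attributions use exact TreeSHAP for gradient-boosted trees and the
closed-form linear decomposition $\phi_j = \beta_j (x_j - \bar{x}_j)$ on
the link scale for (regularized) logistic models; both reconstruct the
model output from the attributions plus base value, which is tested. For
random forests no exact decomposition is available here, and the function
falls back to permutation importance with a logged notice.

For the plain logistic path used inside the bootstrap, the package carries
a compiled IRLS solver (RcppArmadillo) that warm-starts each resample's
refit from the full-data coefficients; a ridge that scales with $n$ (at
$10^{-7} n$, shrinkage is far below estimation noise) keeps the normal
equations well-posed when one-hot blocks are collinear with the intercept.

## Trimming, bootstrap, diagnostics

Symmetric trimming retains episodes with $0.05 \le e(X) \le 0.95$ (closed
interval — "between" is read inclusively, and the boundary convention is
pinned by tests). Confidence intervals are **percentile bootstrap** over
person-level resamples: persons are drawn with replacement carrying all
their episodes, the nuisance models are refit per replicate at the chosen
hyperparameters, trimming is re-applied per replicate, and the estimate
recomputed; 1000 replicates by default, 100–200 in the repeated-simulation
studies. Refitting and re-trimming inside the replicate propagate nuisance
estimation uncertainty into the interval, which is what makes the nominal
level attainable. An interval is *significant* when it excludes the
risk-difference null of 0 (the null is 0, not 1, on the additive scale;
a null of 1 belongs to ratio estimands).

Negative-control outcomes — fibrocystic breast disease, hernia, fracture,
none plausibly affected by antibiotic choice — are estimated with the full
machinery at 1 and 3 months (30/90 days). Any interval excluding zero
flags residual bias; across many controls a ~5% false-alarm rate is the
nominal behavior, and the two windows of one control share events and so
fail together, not independently.

## The synthetic-claims generator

Real claims are private, so the package ships a structural causal model
that emits the seven OMOP-shaped tables with a hidden truth table. Per
person: sex (90% female), age $\mathcal{N}(51.7, 20.1^2)$ truncated to
[18, 95], chronic comorbidities whose prevalence rises with age, provider
specialty, an optional prior-year UTI, and one index UTI episode uniform
over the admissible study days. Standardized confounders (age, calendar
time, comorbidity count, internal-medicine specialty, prior UTI) drive
three logits: treatment assignment, control-arm outcome risk, and a
per-30-day disenrollment hazard that may additionally depend on treatment
and its interactions with age and comorbidity. The treatment effect is
additive on the risk scale, so the marginal ATE equals the configured risk
difference δ exactly whenever clamping $p_0 + \delta$ into $[0,1]$ never
binds; configs where clamping would touch more than 1% of episodes are
rejected, because the truth would silently drift from δ. Potential
outcomes are drawn with one shared uniform per episode and stored, giving
downstream stages an exact oracle (`true_ate()`).

Two presets define the validation conditions. `sim_config_confounded()`
makes comparator recipients older, sicker and earlier-era — the baseline
imbalance pattern characteristic of real antibiotic-choice cohorts — with
moderate coefficients so propensities stay roughly within
[0.27, 0.79]: strong enough that the naive contrast is biased by about
seven percentage points, tame enough that inverse weights keep the
estimator's Monte-Carlo error near $4\times10^{-3}$ at 50 000 persons.
`sim_config_censored()` adds informative disenrollment (~25% lose 30-day
follow-up) whose age dependence differs sharply by arm while hazards stay
inside about [0.07, 0.85]. Both choices are deliberate positivity
decisions: an earlier draft that censored sick treated patients at
near-certainty sent observation probabilities toward zero and the weight
variance with it, which is a property of the design, not of the estimator.
Dispensings are written on the index day so that treatment ascertainment
cannot depend on how soon a person disenrolls.

What the generator does *not* emulate: real ICD/NDC vocabularies, visit
billing structure, seasonal and regional patterns, treatment-effect
heterogeneity, and outcome-dependent health-seeking behavior. Passing the
validation suite therefore demonstrates that the pipeline recovers known
truth under the stated causal structure — not that any particular clinical
conclusion transfers to a given payer's data.

## Problem sizes and numerical choices in the validation studies

The simulation studies use sizes chosen to give each check clear
resolution at interactive cost: bias checks run at 50 000 persons × 3
seeds (estimator Monte-Carlo error ≈ 0.004, so a ±0.005 band on the
3-seed mean is discriminating); bootstrap calibration runs 200 simulations
of 5 000 persons with 200 person-level replicates each, per effect size;
negative-control behavior is checked over 20 repetitions of 4 000 persons.
Repeated-simulation studies use a compact confounder design — the
chronic-condition window indicators collapsed to a comorbidity count,
which still spans the generator's structural models — purely to keep tens
of thousands of within-bootstrap refits cheap; single-run analyses use the
full expert matrix.

All randomness descends from one seed per entry point through fixed
stage-derived substreams, and identical config + seed reproduce output
tables byte for byte; xgboost and ranger run single-threaded with fixed
seeds for the same reason.

## Known limitations

Estimation is by weighting only — no augmented/doubly-robust estimator, so
consistency needs the relevant nuisance model (not both) to be correctly
specified, and no survival-time estimands: outcomes are binary within
fixed windows, matching the fixed-window endpoint definitions. The
attrition report's per-rule counts depend on the documented rule order
(the eligible set does not). The percentile bootstrap can undercover
slightly at small replicate counts; the calibration study quantifies this
at the sizes used. Negative-control passes bound *detected* residual
confounding, not all of it.

## A minimal end-to-end run

```{r}
library(uticausal)

bundle <- simulate_claims(sim_config_confounded(n_persons = 10000, seed = 1))
report <- run_contrast(
  bundle,
  endpoints = default_endpoints()["composite_failure"],
  est_cfg = estimator_config(n_bootstrap = 200, seed = 1)
)
report$results              # adjusted risk difference with bootstrap CI
report$naive                # unadjusted contrast, for comparison
report$negative_controls    # residual-bias diagnostics
true_ate(bundle)            # the simulator's ground truth
```
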
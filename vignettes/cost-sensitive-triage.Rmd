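---
title: "Cost-sensitive three-tier triage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-sensitive three-tier triage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costtriage)
```

## The triage problem and the label space

Postoperative neurosurgical patients are allocated to one of three ordered
monitoring tiers — regular ward, intermediate care (IMC), intensive care
(ICU) — encoded `WARD = 0 < IMC = 1 < ICU = 2` throughout the package.
The required tier is defined operationally from postoperative events: the
ICU can manage both ICU-level events (reintubation, catecholamine support,
CPR, …) and IMC-level events (seizures, i.v. antihypertensives, new
cranial-nerve deficits, …); the IMC manages only IMC-level events; the ward
manages neither. Hence `derive_labels()` assigns ICU to any patient with at
least one ICU event regardless of IMC events, IMC to patients with IMC
events only, and ward otherwise — a rule that is monotone in the event
sets.

Under-triage (assigned below the required tier) is the harm-side error;
over-triage the resource-side error. The package's purpose is to make this
asymmetry an explicit, tunable part of model training rather than an
afterthought of threshold fiddling.

## Cost model

Two ingredients enter the training cost matrix `C[true, assigned]`:

* **Resource cost (RC).** Nurse-to-patient ratios — ward 10:1, IMC 4:1,
  ICU 2:1 by default — are a transparent proxy for nursing intensity.
  With `r_j = 1/ratio_j`, every row of RC is `r / sum(r)`
  (≈ 0.118/0.294/0.588). The cost depends only on the *assigned* level and
  is charged on the diagonal too: a correctly assigned ICU patient still
  occupies an ICU bed. This nonzero diagonal is essential for the
  resource-dominant regime in which even true ICU cases are sent to the
  ward; a zero-diagonal resource matrix could not produce it. RC is not a
  monetary microcosting — it deliberately omits physician staffing,
  equipment and opportunity costs.
* **Harm cost (HC).** Only under-triage cells are penalized, with weights
  proportional to the inverse frequency of the true class and scaled so
  the maximum entry is 1. Scaling to 1 makes the ζ units comparable across
  cohorts with different class mixes. With the default class mix
  (62.9/24.7/12.4 %), missing an ICU patient costs 1 at either lower tier
  and missing an IMC patient 0.502.

The blend is `C(ζ) = exp(−ζ)·RC + exp(ζ)·HC`, normalized by its maximum
entry. The exponential weights are smooth, symmetric about ζ = 0, and span
the full regime change over ζ ∈ [−5, 5]: at ζ = −5 the cheapest column for
every true class is the ward; at ζ = +5 the ICU under-triage cells dominate
the matrix. The blend lives in a single function (`combine_cost()`) so that
an institution preferring another parameterization can drop in a
replacement without touching the learner. One fine point: after
normalization the two ICU under-triage cells tie at the top in the
harm-dominant limit, separated only by the residual resource term (which is
marginally larger for the IMC column) — tests assert the regime behaviour,
not a strict ordering between those two cells.

## The expected-cost objective

Training minimizes the expected misclassification cost. For raw scores `z`
with `p = softmax(z)`, true class `y` and cost row `c = C[y, ]`:

* loss `L = Σ_k p_k c_k`,
* gradient `g_j = p_j (c_j − S)` with `S = Σ_k p_k c_k`,
* diagonal Hessian `h_j = p_j (c_j − S)(1 − 2 p_j) = g_j (1 − 2 p_j)`.

`Σ_j g_j = 0` identically (softmax shift invariance). The true second
derivative is frequently negative — for instance on the correct class when
its probability is below ½ — and boosted-tree leaf solvers require positive
curvature, so the Hessian is floored at `hessian_floor = 1e-6`, the
standard device for custom multiclass objectives. Both derivatives are
verified against central finite differences (ε = 1e−6, agreement ≤ 1e−6
absolute over 1000 random draws) in the test suite; with a plain 0/1 cost
matrix the objective reduces to ordinary softmax classification and reaches
≥ 99 % training accuracy on separable data.

Two decision rules are provided. `argmax` picks the most probable class —
defensible because training is already cost-aware. `min_expected_cost`
picks `argmin_j Σ_i p_i C[i, j]` and is the rule the ζ-sweep uses in its
fast mode, where cost sensitivity must come from the decision stage. Ties
resolve to the lowest acuity in both rules, a deliberate resource-side
default. Which rule produced a given sweep is recorded in the result.

## Cross-validation and evaluation

The harness is stratified 5-fold cross-validation repeated 5 times
(25 runs). Folds are dealt round-robin within each class after shuffling,
so per-fold class counts deviate from proportionality by at most one
patient; every patient is held out exactly once per repeat; everything is
deterministic given the seed (single learner thread, seeded subsampling).
External evaluation applies all 25 fitted models to an independent cohort
and reports each metric's mean ± SD with a 95 % t-interval across models.

Discrimination is summarized by AUCµ, a pairwise multiclass ROC
generalization: for each class pair the samples are scored by a linear
decision statistic built from two rows of a partition matrix, and the
pair's separability is the classical rank-sum AUC of that statistic (ties
count ½, so the two-class restriction is exactly the Mann–Whitney AUC).
AUCµ is their mean over the three pairs. The statistic is oriented so that
the class with the lower index scores higher under the default
0/1 partition; substituting `C(ζ)` for the partition gives the
cost-weighted variant. A per-pair cost weighting is a conceivable
alternative; scoring-vector substitution was chosen because it keeps the
binary restriction exact. F1 is one-vs-rest per class, weighted by
ground-truth support; metrics over CV runs are reported as mean ± SD across
runs rather than pooled-then-scored.

## The ζ sweep and the operating point

`zeta_sweep()` traces allocation fractions, the under/correct/over-triage
rate triple (which sums to 1 by construction) and confusion matrices over a
ζ grid; the reference grids are a coarse Δ0.1 sweep over [−5, 5] and a fine
Δ0.025 sweep over [0.5, 1.5]. Retraining 25 models at every grid point is
cluster-scale work, so the default "decision" mode trains the CV ensemble
once (at `ref_zeta = 0.975`) and re-decides the pooled held-out
probabilities under each `C(ζ)` with the minimum-expected-cost rule; the
"retrain" mode performs the faithful per-ζ retraining and is the mode
required for feature-importance-versus-ζ curves. The mode is stored in the
result because the two are approximations of one another, not equivalents
— on the bundled synthetic cohort the decision-mode transition is centred
below ζ = 0, whereas training-time cost sensitivity shifts it.

The operating-point heuristic is the ζ at which the numerical derivative
(central differences; one-sided at the grid ends; optional odd-width
moving-average smoothing) of the total over-triage rate is maximal — the
knee past which escalation grows faster than under-triage shrinks. Ties
resolve to the smallest ζ, with a small floating-point tolerance so an
exactly linear curve returns the first grid point rather than an arbitrary
interior one. `bootstrap_inflection()` resamples the pooled held-out
(label, probability) pairs with replacement — not the training data — and
reports the inflection distribution, its median (the operating point) and
mean; a `retrain = TRUE` flag exists for the expensive interpretation in
which each replicate re-runs the cross-validation on a resampled cohort.

## Synthetic cohort generator

No patient-level clinical data ships with the package; the generator
provides a controllable testbed with the published marginal structure:

* class priors 62.9 / 24.7 / 12.4 % (ward/IMC/ICU);
* age 56.85 ± 14.71 y, BMI 26.53 ± 4.96, weight 77.91 ± 17.00 as truncated
  normals (plausibility bounds trim the tails, shrinking SDs by ~2 %);
  tumor volume as a log-normal solved by method of moments from
  21.47 ± 31.23 mL (SD > mean implies heavy right skew);
* categorical tables (ASA, GCS, sex, location, diagnosis, comorbidities)
  from the published cohort overview; where printed categories do not sum
  to the full cohort (location: 251 + 789 = 1040 ≠ 1072; GCS similarly)
  the probabilities are renormalized rather than second-guessed;
* surgery duration (240 ± 80 min, truncated at [45, 600]) and surgical
  position (supine/prone/semi-sitting/lateral = 0.55/0.20/0.15/0.10) are
  not printed anywhere and are the package's own choices of realistic
  elective-craniotomy values, fixed once;
* labels via an ordinal-logit link: latent risk
  `z = Σ_f β_f · standardized(f)` (defaults dominated by surgery duration
  1.0 and tumor volume 0.8, then infratentorial location 0.5, age 0.3,
  BMI 0.2) plus standard logistic noise, with cutpoints set at empirical
  quantiles of the latent variable so realized class frequencies match the
  priors exactly up to integer rounding, whatever the marginals;
* event flags sampled per class from the printed event counts,
  renormalized to conditional frequencies (ICU events among the 133
  ICU-class patients, IMC events among the 398 patients at IMC level or
  above), with the modal event forced when no draw fires so derived labels
  always reproduce the planted class.

What the generator does **not** emulate: the joint correlation structure of
real perioperative data (features are drawn independently), site-specific
event definitions, and any nonlinear or interaction structure in the true
risk. Passing tests on this testbed therefore demonstrates that the
machinery is correct and that planted monotone signal is recovered — not
that any particular discrimination level is attainable on real cohorts.
Consistently, the synthetic cohort's over-triage knee need not sit at the
clinically reported ζ ≈ 0.975; the bootstrap machinery reports wherever it
actually is.

All randomness flows from one master seed through R's default generator in
a fixed draw order, so cohorts are bit-reproducible across platforms.

## Cohort-comparison statistics

`compare_cohorts()` reproduces the published two-cohort tables: Fisher's
exact test (two-sided by the point-probability rule) for binary variables
and event rows, Pearson chi-square without continuity correction for
categoricals with ≥ 3 observed levels (variables that collapse to two
observed levels re-route to Fisher; all-empty levels are dropped), and
Welch's t-test computed from (n, mean, SD) summaries — the only form
possible when sources print summaries rather than raw data; rounded inputs
limit agreement with published p-values to roughly the second or third
decimal, while the Fisher values reproduce to all four printed decimals.
The battery reports per-variable failures in a `note` column instead of
aborting.

Null calibration is checked on 200 pairs of cohorts drawn from identical
generator settings at n = 2000 per cohort; the pooled rejection rate at
α = 0.05 lands near 3–4 %, below the nominal 5 % because Fisher's exact
test is conservative on discrete tables — rare events (e.g. CPR at ~0.4 %
prevalence) admit few attainable p-values. The cohort size was fixed at
2000 so that rare-event counts are non-trivial; at smaller n the
discreteness would dominate the battery. No multiplicity adjustment is
applied, matching the source tables' presentation.

## Numerical choices and degenerate inputs

* Hessian floor 1e−6; base margin 0 for all classes; single-thread,
  seeded learner.
* Softmax is computed with max-subtraction; probability rows sum to 1
  within 1e−12.
* Decision ties → lowest acuity; inflection ties → smallest ζ (with fp
  tolerance 1e−9 relative to the derivative scale).
* `fisher_exact_2x2()` clamps at 1 (the underlying implementation can
  overshoot by an ulp); chi-square refuses tables with zero expected
  counts and advises pooling.
* Readers reject, never impute: any blank cell fails with the offending
  `patient_id`; unknown category values fail with the vocabulary;
  duplicated ids, non-positive ages/durations, GCS outside 3–15 all error.
* A cohort too small to realize all three classes generates with a
  warning; cross-validation refuses cohorts with fewer members of any
  class than folds.
* Hyperparameter search is a seeded random search (default budget 25
  trials, inner 3-fold CV, scored by held-out expected cost) — a
  desk-scale stand-in for large sequential optimizations; its best-so-far
  score is monotone in the budget for a fixed seed stream.

## Problem sizes used by the test suite

The suite exercises generation at up to n = 10⁵ (prior convergence),
training at n = 2000 with 5×5 CV (regime behaviour), 10 seeds × n = 2000
single fits (importance recovery), 200 × 2 cohorts at n = 2000 (null
calibration), and exact O(n²) metric oracles at n ≤ 500. These sizes were
chosen so the whole suite completes in a few minutes on a single CPU while
keeping every statistical check adequately powered.

## Known limitations

* The ζ-blend is one defensible parameterization of the resource/harm
  trade-off; published work built on the same idea may use a different
  functional form behind the same limiting behaviour.
* Decision-mode sweeps approximate per-ζ retraining; conclusions about
  *where* the knee sits depend on the mode and are labelled as such.
* Feature matrices integer-code nominal categoricals (trees absorb this at
  the cost of extra splits); one-hot encoding would change gain/SHAP
  bookkeeping but not the framework.
* The generator's independence assumption understates real-world feature
  collinearity (e.g. long operations and large tumors co-occur), which
  matters for interpreting SHAP rankings on real data.
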
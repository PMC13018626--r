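# costtriage

Cost-sensitive three-tier postoperative triage modelling for neurosurgical
cohorts.

## The problem

After elective cranial tumor surgery, every patient must be allocated to a
monitoring tier: regular **ward**, **intermediate care (IMC)**, or
**intensive care (ICU)**. The two error directions are not symmetric:
*under-triage* (a patient who goes on to need ICU-level intervention sitting
on a ward) risks delayed recognition of deterioration, while *over-triage*
burns scarce nursing capacity on patients who needed only routine
observation. Binary ICU/non-ICU risk scores ignore the middle tier and
optimize statistical error, not operational cost.

`costtriage` treats triage as a three-class, cost-sensitive learning
problem for gradient-boosted trees, with a single tunable lever for the
resource/harm trade-off.

## The model

Classes are ordered `WARD = 0 < IMC = 1 < ICU = 2`. Two 3×3 cost matrices
(rows = true class, columns = assigned class) encode the trade-off:

- **RC** (resource cost): nurse-to-patient ratios (ward 10:1, IMC 4:1,
  ICU 2:1) give per-level staffing intensity `r_j = 1/ratio_j`;
  `RC[i, j] = r_j / Σ_k r_k` for every true class `i` (a correct ICU
  assignment still consumes ICU staffing). Rows sum to 1.
- **HC** (harm cost): under-triage cells only, weighted by inverse class
  frequency and scaled to max 1:
  `HC[i, j] = (1/f_i) / max_k (1/f_k)` for `j < i`, else 0.

The training matrix is the ζ-weighted blend

```
C(ζ) = e^(−ζ)·RC + e^(ζ)·HC,  normalized by its maximum entry.
```

Training minimizes the **expected misclassification cost**: with softmax
probabilities `p = softmax(z)` and true class `y`,

```
L(z, y) = Σ_k p_k · C[y, k]
g_j = p_j (C[y, j] − S),   h_j = g_j (1 − 2 p_j),   S = Σ_k p_k C[y, k]
```

supplied to xgboost as a custom multiclass objective (Hessian floored at
1e−6). Sweeping ζ from −5 to +5 moves the fitted policy from
"send everyone to the ward" to "escalate everyone"; the operating point is
chosen as the bootstrap-stable ζ at which the derivative of the total
over-triage rate is maximal (the diminishing-returns knee).

Also included: a seeded synthetic cohort generator emulating a published
neurosurgical cohort's marginals and class mix (62.9 % ward / 24.7 % IMC /
12.4 % ICU), the AUCµ multiclass ROC generalization with a cost-matrix
hook, weighted/per-class F1, gain and mean-|SHAP| feature importance, and a
cohort-comparison battery (Fisher exact, r×2 chi-square, Welch t from
summary statistics).

## Worked example

```r
library(costtriage)

co <- generate_cohort(generator_config(n = 2000, seed = 42))
class_frequencies(co)
#> [1] 0.6290 0.2470 0.1240

rc <- build_rc()                       # ward 10:1, IMC 4:1, ICU 2:1
hc <- build_hc(class_frequencies(co))
sw <- zeta_sweep(co, rc, hc, seq(-5, 5, 0.5), cv_config(seed = 42))
subset(sw$table, zeta %in% c(-5, 0, 5),
       c(zeta, frac_ward, frac_imc, frac_icu, under, correct, over))
#>    zeta frac_ward frac_imc frac_icu  under correct  over
#> 1    -5         1   0.0000   0.0000 0.3710  0.6290 0.000
#> 11    0         0   0.2526   0.7474 0.0061  0.1459 0.848
#> 21    5         0   0.0000   1.0000 0.0000  0.1240 0.876
```

At ζ = −5 the resource term dominates and every patient is assigned to the
ward (all IMC/ICU patients under-triaged, 37.1 % of the cohort); at ζ = +5
the harm term dominates and everyone is escalated to ICU. In between the
allocation mix shifts; on this synthetic cohort the transition is centred
below ζ = 0 (`inflection_point(sw)` returns −0.5 here), and
`bootstrap_inflection()` gives the knee's resampling distribution.

```r
m <- fit_cost_model(cohort_feature_matrix(co), derive_labels(co),
                    combine_cost(rc, hc, 0.975), cv_config(), seed = 1)
head(sort(gain_importance(m), decreasing = TRUE), 3)
#>     surgery_duration         tumor_volume tumor_location_infra
#>            275.89732            119.57946             22.66169
```

Surgery duration and tumor volume — the generator's planted dominant
predictors — carry most of the split gain, mirroring the feature ranking
reported for real cohorts.

A command-line wrapper is installed at `inst/cli/costtriage.R` with
subcommands `simulate`, `train`, `sweep`, `evaluate`, `explain` and
`cohort-stats`; every run writes a JSON manifest sufficient to regenerate
its outputs.

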
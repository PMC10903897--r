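# maihda

Intersectional MAIHDA — **m**ultilevel **a**nalysis of **i**ndividual
**h**eterogeneity and **d**iscriminatory **a**ccuracy — for binary health
outcomes, built as a complete, tested pipeline: from raw survey-style child
and household records, through derived social-determinant variables, to
intersectional strata, a sequence of two-level Bayesian logistic models,
discriminatory-accuracy metrics and ranked stratum-level estimates.

## Who this is for

Epidemiologists and social scientists studying how social determinants of
health (SDoH) — ethnicity, wealth, migration status, education, food
security, catastrophic health spending, and so on — *combine* to pattern
binary outcomes such as childhood diarrhea, fever or cough. Classical
regression treats these determinants additively; the MAIHDA approach
instead cross-classifies them into **intersectional strata** (e.g. *child
under 2 × Luo-headed household × poor tertile × new migrant*) and treats
stratum membership as a random classification above individuals.

## The model

For child *i* in stratum *j*:

```
y_ij ~ Bernoulli(p_ij)
logit(p_ij) = x_ij' beta + u_j,      u_j ~ Normal(0, sigma_u^2)
```

Three models are fitted per outcome:

* **Model 1** (null): intercept + stratum effects only;
* **Model 2**: adds the strata-defining variables as main effects;
* **Model 3**: adds all screened candidate covariates.

Discriminatory accuracy of the strata classification is quantified by

* **VPC** (variance partitioning coefficient):
  `VPC = 100 * sigma_u^2 / (sigma_u^2 + 3.29)`, with 3.29 the fixed
  level-1 latent logistic variance (pi^2/3);
* **PCV** (proportional change in variance):
  `PCV = 100 * (V_model1 - V_modelk) / V_model1` — the share of the null
  model's between-strata variance explained by main effects; the remainder
  is read as intersectional (interaction) effects;
* **AUC-ROC** of the posterior-mean predicted probabilities (stratum
  effects included), computed as the normalised Mann-Whitney statistic.

Models are fitted by a Polya-Gamma-augmented Gibbs sampler (exact conjugate
updates, no tuning), with weakly informative priors: Normal(0, 5^2) on
log-odds coefficients and half-t(3, 0, 2.5) on `sigma_u`. Convergence is
monitored by split R-hat and bulk effective sample size.

Because the survey data the design emulates are not redistributable, the
package ships a synthetic-cohort generator (`cohort_config()`,
`simulate_cohort()`, `slum_cohort_config()`) with fully known ground truth
— fixed effects, between-strata variance, injected interaction effects,
household expenditures with a controllable catastrophic-expenditure rate,
and controllable missingness — against which the whole pipeline is
validated.

## Worked example

```r
library(maihda)

run <- run_maihda_pipeline(list(
  seed = 7,
  input = list(mode = "synthetic", preset = "cough", n = 2199, sigma_u = 0.25),
  outcomes = "cough",
  mcmc_profile = "test"
))
print(run$cough$drop_report)
print(run$cough$da)
```

which prints (numbers from this exact call):

```
Complete-case analysis sample for cough: 1,823 records after 376 (17.1%) were dropped;
of which 170 (7.7%) were due to missing outcomes and 206 (9.4%) had missing
values in variables considered for intersectional strata.
Discriminatory accuracy (VPC / PCV / AUC-ROC)
   model strata var VPC % PCV % AUC-ROC % strata N    N
 Model 1       0.29  8.00    NA     63.56       30 1823
 Model 2       0.01  0.34 96.13     62.85       30 1823
 Model 3       0.01  0.41 95.23     64.30       30 1823
```

Read: the null model locates 8% of the latent outcome variance between the
30 intersectional strata built from the covariates that passed univariable
screening at this sample size; adding the strata-defining main effects
explains ~96% of that between-strata variance (PCV), and the residual VPC
of ~0.3% says this synthetic world — generated with additive effects and
only mild stratum noise — has essentially no intersectional structure left.
On a cohort with genuine interaction effects, Model 2's VPC stays above the
5% acceptability threshold instead (this contrast is asserted in the test
suite).
`plot(run$cough$fits[["Model 2"]])` draws the ranked caterpillar plot of
stratum estimates with 95% credible intervals.

Lower-level entry points: `wealth_index()` (asset PCA), `compute_che()`
(catastrophic health expenditure at the 40% capacity-to-pay threshold),
`recode_variables()`, `complete_case_filter()`, `screen_covariates()`,
`cramers_v()`, `build_strata()`, `maihda()` (the model fitter),
`vpc()` / `pcv()` / `auc_roc()`, and `stratum_effects()`.

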
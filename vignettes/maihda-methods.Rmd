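---
title: "Intersectional MAIHDA for binary child-health outcomes: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intersectional MAIHDA for binary child-health outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(maihda)
```

## The question MAIHDA answers

Social determinants of health (SDoH) rarely act one at a time. A child in
an informal settlement may face the joint consequences of belonging to a
marginalised ethnic group, a poor household, a newly migrated family and a
household recovering from catastrophic health spending. Multilevel Analysis
of Individual Heterogeneity and Discriminatory Accuracy (MAIHDA)
operationalises this intersectional view: every observed combination of
determinant categories is a *stratum*, strata are treated as a random
classification (level 2) above individuals (level 1), and the analysis asks
(i) how much of the outcome variation sits *between* strata, (ii) how much
of that is explained by the determinants acting additively, and (iii) which
strata sit above or below their additive expectation.

## Model sequence

For child $i$ in stratum $j$,

$$y_{ij} \sim \text{Bernoulli}(p_{ij}), \qquad
\text{logit}(p_{ij}) = \mathbf{x}_{ij}'\boldsymbol\beta + u_j, \qquad
u_j \sim N(0, \sigma_u^2).$$

* **Model 1** — intercept and $u_j$ only. Its $\sigma_u^2$ measures total
  between-strata clustering.
* **Model 2** — adds the strata-defining variables as main effects. If
  determinants act purely additively, Model 2's $\sigma_u^2$ collapses
  towards zero.
* **Model 3** — adds all candidate covariates (screened or not), guarding
  against confounding by variables left out of the strata definition.

The residual $u_j$ of Models 2–3 is the *intersectional effect*: a positive
posterior mean says children in that stratum do worse than the sum of their
parts predicts.

### Discriminatory accuracy

* `vpc(sigma2)` returns $100\,\sigma_u^2 / (\sigma_u^2 + 3.29)$. The
  level-1 variance of the latent-logistic formulation is $\pi^2/3 \approx
  3.2899$; we hard-code the conventional two-decimal constant **3.29** so
  that reported values reproduce published worked examples digit for digit
  — the difference is negligible but reproducibility beats elegance. Values
  above 5% are labelled *acceptable* discriminatory accuracy (strictly
  greater than 5: a VPC of exactly 5.0% is not acceptable).
* `pcv(v1, vk)` returns $100\,(V_1 - V_k)/V_1$, the share of the null
  model's between-strata variance explained by fixed effects. It can be
  negative if variance rises.
* `auc_roc(y, p)` is the normalised Mann–Whitney statistic computed from
  midranks (ties get 1/2 credit). Predictions are the posterior-mean
  probabilities *including* $u_j$: the paper trail of a fitted two-level
  model is its full linear predictor, and this convention is what makes the
  null model's AUC far exceed 0.5 whenever strata cluster. AUC bands:
  below 0.6 poor, 0.6–0.7 weak, 0.7–0.8 good, 0.8 and above excellent.

Both VPC and PCV are computed from full-precision posterior medians, never
from rounded intermediate values; two-decimal published tables can
therefore disagree with recomputed cells by rounding alone.

## Prior, sampler and convergence

Published MAIHDA analyses typically say only "weakly informative priors".
The defaults here are $\beta \sim N(0, 5^2)$ on the log-odds scale and
$\sigma_u \sim$ half-$t(3, 0, 2.5)$ — standard weakly informative choices
for multilevel logistic models; both are arguments of `maihda_prior()`.

`maihda()` samples by Pólya-Gamma data augmentation: given
$\omega_{ij} \sim \text{PG}(1, \eta_{ij})$ the logistic likelihood becomes
Gaussian in $(\boldsymbol\beta, \mathbf{u})$, so every update is an exact
conjugate draw — no step-size tuning, robust with hundreds of singleton
strata. The half-$t$ prior is implemented through its inverse-gamma scale
mixture so the variance update is conjugate too. PG variates are drawn by
the exact alternating-series rejection sampler (Devroye-style) implemented
in `src/pg.cpp`; the test suite checks it against closed-form moments and
an independent truncated sum-of-gammas construction.

Any sampler meeting the same validation contract (coverage, null recovery,
diagnostics) would be acceptable; this one was chosen because exactness and
tuning-freeness matter more than raw speed at these problem sizes.

* **Iterations**: the default `maihda_mcmc()` profile is 20,000 iterations
  per chain with 2,000 burn-in (the convention for these analyses), four
  chains, thinning 10. The `"test"` profile (4,000/500, two chains,
  thinning 2) is used throughout the test suite; the package's validation
  studies showed nominal coverage already at this length.
* **Initialisation**: $\beta = 0$, $u = 0$, $\sigma_u = 1$, jittered per
  chain with the chain index folded into the seed.
* **Convergence**: split R-hat and bulk ESS are computed for all fixed
  effects and $\sigma_u^2$; any R-hat above 1.05 flags the fit
  non-converged (returned, but warned about). This replaces — and is
  stricter than — purely graphical checks; trace material is available from
  the stored draws.

## Building the analysis variables

* **Wealth index** (`wealth_index`): first principal component of the
  *standardised* asset indicators (PCA on the correlation matrix — the
  standard asset-index choice when binary indicators have unequal
  variances), sign-oriented so owning more assets raises the score,
  quintiles cut at the 20/40/60/80th percentiles, then collapsed
  quintiles {1,2} → poor, {3} → middle, {4,5} → rich. The collapse and the
  tie rule (a score exactly at a cutpoint goes to the lower category) are
  fixed conventions, both overridable.
* **Catastrophic health expenditure** (`compute_che`): the WHO/Xu
  capacity-to-pay procedure with equivalence-scale exponent 0.56 and the
  45th–55th food-share percentile band for the subsistence line; a
  household is flagged when out-of-pocket health spending is **at least**
  40% of capacity to pay (the boundary is inclusive). Degenerate cases:
  non-positive capacity to pay excludes the record with a logged count; an
  empty food-share band is widened symmetrically in 5-point steps until
  non-empty. Both parameters are arguments.
* **Recodes** (`recode_variables`): child age under 24 months is "1 year
  and less"; a stay of exactly 2 years is still a "new migrant"; mothers
  aged 18 or less form their own category because births below the age of
  consent mark child mothers. Out-of-range raw values flag the row invalid
  rather than silently clamping.
* **Complete cases** (`complete_case_filter`): rows missing the outcome
  are dropped first and counted, then rows missing any modelled covariate —
  the same accounting order used in survey reports. No imputation, by
  design; the generator's missingness is MCAR, which is the assumption
  under which complete-case analysis is unbiased.

## Strata construction

Candidates are screened one at a time by the likelihood-ratio test of the
univariable logistic model against the intercept-only model (`"chisq"`
switches to the Pearson test); selection is strict ($p < \alpha$, so
$p = \alpha$ exactly is *not* selected). Pairwise Cramér's V above 0.5
triggers a warning and drops the variable with the weaker screening
p-value — published analyses state the Cramér's V step without a cutoff, so
the threshold is an explicit, documented, overridable default. Strata are
the *observed* cross-classifications only, IDs assigned in lexicographic
order; if nothing passes screening the builder stops and asks for an
explicit variable list (theory-driven strata remain available through that
override).

## The synthetic-cohort generator

`cohort_config()` + `simulate_cohort()` generate cohorts from the exact
two-level model above, with every parameter recorded in a truth object:
covariates drawn from stated marginals (independent by default; a joint
table hook exists because real SDoH correlate), one $u_j$ per realised
stratum, optional interaction effects $\delta$ injected for named
level-combinations, log-normal/Beta household expenditures with a
calibratable CHE rate, and MCAR missingness using the survey sentinel
`NA_NOTAPP` at the CSV boundary.

`slum_cohort_config()` freezes the package's reference conditions: 2,199
children; the documented category sets with plausible slum-survey
marginals; prevalences near 17–25% depending on outcome; $\sigma_u = 0.2$
($\sigma_u^2 = 0.04$, inside the 0.03–0.41 range typical of such
outcomes); ~8% missing outcomes and ~8% further covariate drops; and
strata geometries of roughly 750 sparsely populated strata (nine defining
variables) down to ~80 well-populated strata (four variables). These
marginals are design choices, not estimates — the real survey microdata are
not redistributable — so passing tests demonstrate the *method* recovers
known truth under realistic geometry, not that any specific real-world
coefficient is reproduced. Features of real data the generator does not
emulate: survey design (clusters, weights), correlated determinants (unless
opted into), informative missingness, and measurement error in recall-based
outcomes.

## Validation studies shipped in the test suite

All sizes were chosen to exercise the claims at desk scale:

* **Coverage**: 20 replicates of $n = 10{,}000$, $J = 50$,
  $\beta_0 = -1.5$, $\sigma_u = 0.6$, at the test MCMC profile; 95%
  credible intervals for $\beta_0$ and $\sigma_u^2$ must cover truth at
  least 90% of the time.
* **Null recovery**: $\sigma_u = 0$, $n = 10{,}000$, $J = 50$: posterior
  median $\sigma_u^2 < 0.05$ and at most 7.5% of strata flagged
  significant.
* **Additive vs interaction discrimination**: 20 replicates each of a
  purely additive world (PCV of Model 2 approaches 100%, residual VPC
  small) and a world with $\delta = 1$ interactions (Model-2 VPC above the
  5% acceptability threshold), $n = 2{,}000$, $J = 32$.
* **Oracle equalities**: AUC vs brute-force pairwise comparison, Cramér's V
  vs hand-computed tables, stratum grouping vs a nested-loop oracle,
  posterior quantiles vs sort-based quantiles, the PG sampler vs closed-form
  moments and the sum-of-gammas construction, and the full Xu procedure on
  a six-household table worked by hand (including the inclusive 40%
  boundary).
* A frequentist cross-check: posterior centres agree with `lme4::glmer` on
  a moderate cohort.

## Numerical conventions and edge cases

* The VPC constant is 3.29 exactly (see above).
* Quantile ties at quintile/percentile cutpoints go to the lower category.
* Stratum-effect ranks are ascending by posterior mean; exact ties are
  broken by stratum ID. Significance = the equal-tailed 95% interval
  excludes 0; the summary statistic is the posterior mean (median via
  `stat = "median"`).
* `cramers_v` of a constant vector is defined as 0 with a warning; the
  chi-square statistic is uncorrected.
* Degenerate fits (all-0 or all-1 outcome) error; quasi-separation warns
  but still reports the likelihood-ratio p-value; fixed-effect levels with
  zero cases in a class trigger a separation-risk warning.
* Everything downstream of a seed is reproducible bit-for-bit, including
  serialised CSV/JSON artifacts; the pipeline manifest records an MD5 hash
  of the configuration.

## Known limitations

* No survey weights or design effects — the analysis is unweighted by
  scope.
* No frequentist fitting path, and no WAIC/LOO model comparison.
* In-sample AUC only (no cross-validation).
* MCAR missingness only in the generator; MAR/MNAR sensitivity is out of
  scope.
* MAIHDA is exploratory: strata here come from a screening heuristic, not
  from theory; the stratum-variable override exists precisely so
  theory-driven strata can be supplied.
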
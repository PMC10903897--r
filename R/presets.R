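#' Default synthetic-cohort configuration emulating a slum child-health survey
#'
#' A ready-made [cohort_config()] whose structure mirrors the cross-sectional
#' slum survey the analysis pipeline was designed around: 2,199 children
#' under five; the categorical social-determinant variables and level sets
#' of [analysis_levels()]; outcome prevalences in the 17-25% range;
#' between-strata variance on the latent scale inside the 0.03-0.41 range
#' seen for such outcomes; and missingness rates giving roughly 8% missing
#' outcomes plus a further ~8% of rows missing some covariate. The
#' `"diarrhea"` flavour defines strata over nine variables (hundreds of
#' sparsely populated strata); `"cough"` over four (a few dozen
#' well-populated strata); `"fever"` over seven. Marginals and effects are
#' package defaults chosen as plausible for such a survey, not estimates
#' from any real data.
#'
#' @param outcome which outcome flavour to emulate.
#' @param n number of children.
#' @param seed integer seed.
#' @param sigma_u between-strata SD (logit scale).
#' @param interactions optional injected intersectional effects (see
#'   [cohort_config()]).
#' @param missing_rates per-field MCAR rates; `NULL` for complete data.
#' @return a `maihda_sim_config`.
#' @export
slum_cohort_config <- function(outcome = c("diarrhea", "fever", "cough"),
                               n = 2199, seed, sigma_u = 0.2,
                               interactions = list(),
                               missing_rates = slum_missing_rates(outcome)) {
  outcome <- match.arg(outcome)
  lv <- analysis_levels()
  covariates <- list(
    child_age = setNames(c(0.33, 0.67), lv$child_age),
    child_sex = setNames(c(0.49, 0.51), lv$child_sex),
    mother_age = setNames(c(0.07, 0.93), lv$mother_age),
    mother_education = setNames(c(0.62, 0.30, 0.08), lv$mother_education),
    head_sex = setNames(c(0.28, 0.72), lv$head_sex),
    head_age = setNames(c(0.15, 0.45, 0.40), lv$head_age),
    head_ethnicity = setNames(c(0.21, 0.27, 0.25, 0.19, 0.08), lv$head_ethnicity),
    head_education = setNames(c(0.04, 0.87, 0.09), lv$head_education),
    wealth = setNames(c(0.35, 0.33, 0.32), lv$wealth),
    length_of_stay = setNames(c(0.20, 0.66, 0.14), lv$length_of_stay),
    religion = setNames(c(0.21, 0.70, 0.09), lv$religion),
    tenure = setNames(c(0.08, 0.92), lv$tenure),
    food_security = setNames(c(0.57, 0.43), lv$food_security),
    health_insurance = setNames(c(0.88, 0.12), lv$health_insurance),
    income_activity = setNames(c(0.44, 0.34, 0.22), lv$income_activity),
    che = setNames(c(0.86, 0.14), lv$che)
  )
  spec <- switch(outcome,
    diarrhea = list(
      beta0 = -3.26,
      betas = list(
        child_age = c("2-5 years" = -0.37),
        head_ethnicity = c(Kikuyu = 0.18, Luhya = 0.62, Luo = 0.48,
                           other = 0.21),
        head_education = c(educated = 0.81,
                           "don't know/not applicable" = 0.90),
        wealth = c(middle = 0.54, poor = 0.31),
        length_of_stay = c("old migrants" = -0.31,
                           "missing/not applicable" = -0.45),
        religion = c(protestant = 0.29, other = -0.24),
        health_insurance = c(yes = -0.36),
        food_security = c("not enough" = 0.23),
        tenure = c("pays rent" = 0.60)
      ),
      strata_vars = c("child_age", "head_ethnicity", "head_education",
                      "wealth", "length_of_stay", "health_insurance",
                      "religion", "food_security", "tenure")
    ),
    fever = list(
      beta0 = -1.94,
      betas = list(
        child_sex = c(male = -0.27),
        head_ethnicity = c(Kikuyu = 0.42, Luhya = 1.07, Luo = 0.71,
                           other = 0.89),
        mother_age = c("19-49 years" = -0.34),
        wealth = c(middle = 0.32, poor = 0.16),
        che = c(yes = 0.69),
        length_of_stay = c("old migrants" = -0.26,
                           "missing/not applicable" = -0.41),
        food_security = c("not enough" = 0.25)
      ),
      strata_vars = c("child_sex", "head_ethnicity", "mother_age", "wealth",
                      "che", "length_of_stay", "food_security")
    ),
    cough = list(
      beta0 = -1.67,
      betas = list(
        head_ethnicity = c(Kikuyu = 0.48, Luhya = 0.97, Luo = 0.82,
                           other = 0.82),
        wealth = c(middle = 0.25, poor = 0.17),
        length_of_stay = c("old migrants" = -0.46,
                           "missing/not applicable" = -0.40),
        che = c(yes = 0.66)
      ),
      strata_vars = c("head_ethnicity", "wealth", "length_of_stay", "che")
    )
  )
  cohort_config(
    n = n, covariates = covariates, beta0 = spec$beta0, betas = spec$betas,
    sigma_u = sigma_u, interactions = interactions,
    strata_vars = spec$strata_vars, outcome = outcome,
    missing_rates = missing_rates, seed = seed
  )
}

#' @rdname slum_cohort_config
#' @export
slum_missing_rates <- function(outcome = c("diarrhea", "fever", "cough")) {
  outcome <- match.arg(outcome)
  c(setNames(0.082, outcome),
    head_education = 0.015, wealth = 0.015, religion = 0.01,
    food_security = 0.015, health_insurance = 0.01, che = 0.01,
    mother_age = 0.005, child_sex = 0.005, tenure = 0.005,
    child_age = 0.01, head_ethnicity = 0.01)
}
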
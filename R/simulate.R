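#' Configuration for a synthetic cohort
#'
#' Defines the generative model of the synthetic-cohort generator: a
#' two-level logistic model with known fixed effects, a known between-strata
#' standard deviation and optional injected intersectional interactions, so
#' that every downstream stage of the analysis can be validated against
#' ground truth.
#'
#' @param n number of individuals (children), at least 1.
#' @param covariates named list; each element is a named numeric vector of
#'   marginal probabilities over that covariate's category levels (must sum
#'   to 1), or a list with elements `levels` and `probs`.
#' @param beta0 log-odds intercept.
#' @param betas named list of named numeric vectors: per covariate, the
#'   additional log-odds for each non-reference level (levels omitted have
#'   effect 0).
#' @param sigma_u between-strata standard deviation on the logit scale
#'   (>= 0); one `u_j ~ Normal(0, sigma_u^2)` is drawn per realised stratum.
#' @param interactions list of injected intersectional effects, each a list
#'   with `when` (named character vector of covariate = level conditions)
#'   and `delta` (additional log-odds for individuals matching all
#'   conditions).
#' @param strata_vars covariates whose cross-classification defines the
#'   strata (default: all covariates).
#' @param outcome outcome column name.
#' @param expenditure optional [expenditure_params()] for household
#'   expenditure fields.
#' @param missing_rates optional named vector of per-field MCAR missingness
#'   probabilities applied by [simulate_cohort()].
#' @param joint optional dependence hook: list of lists with `vars` (two
#'   covariate names) and `probs` (joint probability matrix with dimnames
#'   matching the two covariates' levels) replacing independent sampling for
#'   those pairs.
#' @param seed mandatory integer seed.
#' @return list of class `maihda_sim_config`.
#' @export
cohort_config <- function(n, covariates, beta0 = 0, betas = list(),
                          sigma_u = 0, interactions = list(),
                          strata_vars = names(covariates),
                          outcome = "outcome", expenditure = NULL,
                          missing_rates = NULL, joint = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n < 1) stop("n_individuals must be at least 1")
  stopifnot(is.list(covariates), length(covariates) >= 1,
            !is.null(names(covariates)), sigma_u >= 0)
  covariates <- lapply(covariates, function(cv) {
    if (is.list(cv)) {
      stopifnot(length(cv$levels) == length(cv$probs))
      cv <- setNames(cv$probs, cv$levels)
    }
    if (abs(sum(cv) - 1) > 1e-8) stop("marginal probabilities must sum to 1")
    if (any(cv < 0)) stop("marginal probabilities must be non-negative")
    cv
  })
  stopifnot(all(names(betas) %in% names(covariates)),
            all(strata_vars %in% names(covariates)))
  for (v in names(betas)) {
    bad <- setdiff(names(betas[[v]]), names(covariates[[v]]))
    if (length(bad)) {
      stop(sprintf("effect on unknown level '%s' of covariate '%s'", bad[1], v))
    }
    zero <- names(covariates[[v]])[covariates[[v]] == 0]
    hit <- intersect(names(betas[[v]])[betas[[v]] != 0], zero)
    if (length(hit)) {
      warning(sprintf(
        "nonzero effect on zero-probability level '%s' of '%s' (never realised)",
        hit[1], v))
    }
  }
  for (ia in interactions) {
    stopifnot(is.list(ia), !is.null(ia$when), is.numeric(ia$delta))
    stopifnot(all(names(ia$when) %in% names(covariates)))
  }
  structure(list(n = as.integer(n), covariates = covariates, beta0 = beta0,
                 betas = betas, sigma_u = sigma_u,
                 interactions = interactions, strata_vars = strata_vars,
                 outcome = outcome, expenditure = expenditure,
                 missing_rates = missing_rates, joint = joint,
                 seed = as.integer(seed)),
            class = "maihda_sim_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws covariates from the configured marginals (independently across
#' covariates unless a joint table is supplied), assigns each individual
#' the stratum implied by its covariate levels, draws one stratum effect
#' `u_j ~ Normal(0, sigma_u^2)` per realised stratum, and samples the
#' binary outcome from
#' `Bernoulli(plogis(beta0 + sum(betas) + u_j + delta))`. Household
#' expenditure fields are appended when configured, and MCAR missingness is
#' applied last when `missing_rates` is set. Identical seed and
#' configuration give identical output.
#'
#' @param config a [cohort_config()].
#' @return list of class `maihda_cohort`: `data` (one row per child:
#'   covariates, `stratum` ID, outcome, any expenditure fields) and `truth`
#'   (all parameters, the per-stratum `u_j`, per-row linear predictor and
#'   the stratum map).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "maihda_sim_config"))
  set.seed(config$seed)
  n <- config$n
  covs <- config$covariates

  d <- as.data.frame(lapply(covs, function(cv) {
    factor(sample(names(cv), n, replace = TRUE, prob = cv),
           levels = names(cv))
  }))
  # dependence hook: replace chosen pairs by joint sampling
  for (jt in config$joint %||% list()) {
    va <- jt$vars[1]; vb <- jt$vars[2]
    pr <- jt$probs
    stopifnot(abs(sum(pr) - 1) < 1e-8)
    cell <- sample(length(pr), n, replace = TRUE, prob = as.vector(pr))
    d[[va]] <- factor(rownames(pr)[(cell - 1) %% nrow(pr) + 1],
                      levels = names(covs[[va]]))
    d[[vb]] <- factor(colnames(pr)[(cell - 1) %/% nrow(pr) + 1],
                      levels = names(covs[[vb]]))
  }

  st <- build_strata(d, config$strata_vars)
  u <- rnorm(nrow(st$map), 0, config$sigma_u)

  eta <- rep(config$beta0, n)
  for (v in names(config$betas)) {
    b <- config$betas[[v]]
    eff <- b[as.character(d[[v]])]
    eff[is.na(eff)] <- 0
    eta <- eta + unname(eff)
  }
  delta_row <- numeric(n)
  for (ia in config$interactions) {
    hit <- rep(TRUE, n)
    for (v in names(ia$when)) hit <- hit & d[[v]] == ia$when[[v]]
    delta_row[hit] <- delta_row[hit] + ia$delta
  }
  eta <- eta + delta_row + u[st$id]
  y <- rbinom(n, 1, plogis(eta))

  d$stratum <- st$id
  d[[config$outcome]] <- y

  if (!is.null(config$expenditure)) {
    d <- cbind(d, simulate_expenditure(n, config$expenditure))
  }
  if (!is.null(config$missing_rates)) {
    d <- add_missingness(d, config$missing_rates)
  }

  label <- apply(st$map[, st$vars, drop = FALSE], 1, paste, collapse = " / ")
  truth <- list(beta0 = config$beta0, betas = config$betas,
                sigma_u = config$sigma_u, u = setNames(u, label),
                delta = delta_row, eta = eta,
                strata_map = st$map, config = config)
  structure(list(data = d, truth = truth), class = "maihda_cohort")
}

#' @export
print.maihda_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d children, %d realised strata, outcome '%s'\n",
              nrow(x$data), nrow(x$truth$strata_map), x$truth$config$outcome))
  cat(sprintf("  truth: beta0 = %.2f, sigma_u = %.2f, %d interaction effect(s)\n",
              x$truth$beta0, x$truth$sigma_u,
              length(x$truth$config$interactions)))
  invisible(x)
}

#' Household expenditure generator settings
#'
#' Log-normal total expenditure, a Beta-distributed food share of total
#' (which enforces food <= total by construction), a zero-inflated
#' log-normal out-of-pocket (OOP) health expenditure, and household size
#' `1 + Poisson(size_lambda)`. If `che_target` is set, the OOP amounts are
#' rescaled by a single factor so that the realised catastrophic health
#' expenditure fraction at `che_threshold` matches the target (capacity to
#' pay does not depend on OOP, so the rescaling is exact up to ties).
#'
#' @param total_meanlog,total_sdlog log-normal parameters of total
#'   expenditure.
#' @param food_shape1,food_shape2 Beta parameters of the food share.
#' @param oop_meanlog,oop_sdlog log-normal parameters of nonzero OOP.
#' @param p_oop_zero probability of zero OOP spending.
#' @param size_lambda Poisson rate of (household size - 1).
#' @param oop_scale multiplier applied to OOP (0 gives zero OOP throughout).
#' @param che_target optional target CHE fraction.
#' @param che_threshold CHE threshold used for calibration.
#' @param table optional data frame passed through unchanged (hand-specified
#'   expenditures).
#' @return list of class `maihda_expenditure_params`.
#' @export
expenditure_params <- function(total_meanlog = log(15000), total_sdlog = 0.5,
                               food_shape1 = 5, food_shape2 = 5,
                               oop_meanlog = log(500), oop_sdlog = 1,
                               p_oop_zero = 0.3, size_lambda = 2.5,
                               oop_scale = 1, che_target = NULL,
                               che_threshold = 0.40, table = NULL) {
  if (total_sdlog < 0 || oop_sdlog < 0 || food_shape1 <= 0 ||
      food_shape2 <= 0 || size_lambda < 0 || p_oop_zero < 0 ||
      p_oop_zero > 1 || oop_scale < 0) {
    stop("expenditure distribution parameters imply negative or invalid spending")
  }
  structure(as.list(environment()), class = "maihda_expenditure_params")
}

#' Generate (or pass through) household expenditure records
#'
#' @param n number of households.
#' @param params an [expenditure_params()].
#' @param seed optional seed (omit to use the current RNG stream, as
#'   [simulate_cohort()] does).
#' @return data frame with `total_expenditure`, `food_expenditure`,
#'   `oop_health`, `household_size`.
#' @export
simulate_expenditure <- function(n, params = expenditure_params(),
                                 seed = NULL) {
  stopifnot(inherits(params, "maihda_expenditure_params"))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(params$table)) {
    tab <- as.data.frame(params$table)
    stopifnot(all(c("total_expenditure", "food_expenditure", "oop_health",
                    "household_size") %in% names(tab)))
    return(tab)
  }
  total <- rlnorm(n, params$total_meanlog, params$total_sdlog)
  food <- total * stats::rbeta(n, params$food_shape1, params$food_shape2)
  zero <- runif(n) < params$p_oop_zero
  oop <- ifelse(zero, 0, rlnorm(n, params$oop_meanlog, params$oop_sdlog)) *
    params$oop_scale
  size <- 1L + rpois(n, params$size_lambda)
  out <- data.frame(total_expenditure = total, food_expenditure = food,
                    oop_health = oop, household_size = size)
  if (!is.null(params$che_target)) {
    che <- compute_che(out, threshold = params$che_threshold)
    ratio <- ifelse(is.na(che$capacity_to_pay) | che$capacity_to_pay <= 0,
                    0, out$oop_health / che$capacity_to_pay)
    q <- quantile(ratio, probs = 1 - params$che_target, type = 1, names = FALSE)
    if (q <= 0) {
      warning("CHE target not achievable by rescaling (too many zero-OOP households)")
    } else {
      out$oop_health <- out$oop_health * (params$che_threshold / q)
    }
  }
  out
}

#' Inject missing-completely-at-random values
#'
#' Independently sets each targeted field to missing (`NA` in memory; the
#' `NA_NOTAPP` sentinel when written with [write_cohort()]) with its stated
#' probability.
#'
#' @param data cohort data frame.
#' @param rates named numeric vector of per-field missingness rates in
#'   `[0, 1]`.
#' @param seed optional seed (omit to use the current RNG stream).
#' @return the data frame with missingness applied.
#' @export
add_missingness <- function(data, rates, seed = NULL) {
  data <- as.data.frame(data)
  if (is.null(names(rates)) || !all(names(rates) %in% names(data))) {
    stop("rates must be named after columns of the data")
  }
  if (any(rates < 0 | rates > 1)) stop("missingness rates must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  for (v in names(rates)) {
    data[[v]][runif(nrow(data)) < rates[[v]]] <- NA
  }
  data
}

#' Write / read a cohort CSV with the survey's missing-value sentinel
#'
#' @param data cohort data frame.
#' @param path CSV path.
#' @param sentinel missing-value code used in the file.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the data
#'   frame with sentinel values as `NA`.
#' @export
write_cohort <- function(data, path, sentinel = "NA_NOTAPP") {
  write.csv(data, path, row.names = FALSE, na = sentinel)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, sentinel = "NA_NOTAPP") {
  read.csv(path, na.strings = c(sentinel, "NA"), stringsAsFactors = FALSE)
}

#' Write the ground-truth record of a synthetic cohort as JSON
#'
#' @param cohort a `maihda_cohort`.
#' @param path output JSON path.
#' @export
write_truth <- function(cohort, path) {
  stopifnot(inherits(cohort, "maihda_cohort"))
  tr <- cohort$truth
  jsonlite::write_json(
    list(beta0 = tr$beta0, betas = tr$betas, sigma_u = tr$sigma_u,
         u = as.list(tr$u), seed = tr$config$seed,
         n = tr$config$n,
         interactions = tr$config$interactions),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
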
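#' Prior settings for a MAIHDA model
#'
#' Weakly informative defaults for a two-level logistic model: independent
#' Normal(0, `beta_sd`^2) priors on the intercept and fixed-effect log-odds
#' contrasts, and a half-Student-t(`sigma_df`, 0, `sigma_scale`) prior on
#' the between-strata standard deviation (implemented as an inverse-gamma
#' scale mixture, which keeps every Gibbs update conjugate).
#'
#' @param beta_sd prior SD of the fixed effects on the log-odds scale.
#' @param sigma_df degrees of freedom of the half-t prior on `sigma_u`.
#' @param sigma_scale scale of the half-t prior on `sigma_u`.
#' @return list of class `maihda_prior`.
#' @export
maihda_prior <- function(beta_sd = 5, sigma_df = 3, sigma_scale = 2.5) {
  stopifnot(beta_sd > 0, sigma_df > 0, sigma_scale > 0)
  structure(list(beta_sd = beta_sd, sigma_df = sigma_df,
                 sigma_scale = sigma_scale), class = "maihda_prior")
}

#' MCMC settings for a MAIHDA model
#'
#' Defaults match the reporting convention for these models: 20,000
#' iterations per chain with a burn-in of 2,000, four chains, thinning 10.
#' `maihda_mcmc_profile("test")` gives the reduced profile used throughout
#' the package's test suite (4,000 / 500, two chains, thinning 2).
#'
#' @param iterations iterations per chain (including burn-in).
#' @param burnin burn-in iterations discarded per chain.
#' @param chains number of chains (at least 2, for convergence checks).
#' @param thin thinning interval applied after burn-in.
#' @return list of class `maihda_mcmc`.
#' @export
maihda_mcmc <- function(iterations = 20000, burnin = 2000, chains = 4,
                        thin = 10) {
  stopifnot(iterations >= 2, burnin >= 0, burnin < iterations,
            chains >= 2, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin),
                 chains = as.integer(chains), thin = as.integer(thin)),
            class = "maihda_mcmc")
}

#' @rdname maihda_mcmc
#' @param profile `"paper"` (full-length) or `"test"` (reduced).
#' @export
maihda_mcmc_profile <- function(profile = c("paper", "test")) {
  switch(match.arg(profile),
         paper = maihda_mcmc(20000, 2000, 4, 10),
         test = maihda_mcmc(4000, 500, 2, 2))
}

#' Fit a two-level Bayesian logistic MAIHDA model
#'
#' Fits `y_ij ~ Bernoulli(p_ij)`, `logit(p_ij) = x_ij' beta + u_j`,
#' `u_j ~ Normal(0, sigma_u^2)`, with individuals `i` nested in
#' intersectional strata `j`, by Polya-Gamma-augmented Gibbs sampling
#' (exact conjugate conditional updates; no tuning). The model sequence of
#' a MAIHDA analysis is obtained by varying the formula: the null model is
#' `outcome ~ 1`, the main-effects model adds the strata-defining
#' variables, and the fully adjusted model adds all candidate covariates.
#'
#' Chains are initialised at `beta = 0`, `u = 0`, `sigma_u = 1`, jittered
#' per chain with the chain index folded into the seed. A fit with any
#' monitored split R-hat above 1.05 is flagged non-converged (the result is
#' still returned).
#'
#' @param formula model formula, e.g. `diarrhea ~ 1` or
#'   `diarrhea ~ child_age + head_ethnicity`. Factor contrasts are dummy
#'   codes against each factor's first (reference) level.
#' @param data data frame of complete cases.
#' @param strata stratum assignment: a column name in `data`, a vector of
#'   length `nrow(data)`, or a `maihda_strata` object from [build_strata()].
#' @param prior a [maihda_prior()].
#' @param mcmc a [maihda_mcmc()].
#' @param seed integer seed; each chain derives its own stream from it.
#' @param verbose print per-chain progress.
#' @return object of class `maihda_fit`: posterior draws (`draws$beta`,
#'   `draws$u`, `draws$sigma2` with `chain` index), posterior-mean
#'   per-individual probabilities `p_hat` and linear predictor `linpred`,
#'   stratum map, diagnostics (split R-hat, bulk ESS) and `converged` flag.
#' @examples
#' d <- simulate_cohort(cohort_config(
#'   n = 400, covariates = list(g = c(a = 0.5, b = 0.5)),
#'   beta0 = -1, sigma_u = 0.3, seed = 7))
#' f <- maihda(outcome ~ 1, d$data, strata = "stratum",
#'             mcmc = maihda_mcmc(400, 100, 2, 1), seed = 1)
#' print(f)
#' @export
maihda <- function(formula, data, strata, prior = maihda_prior(),
                   mcmc = maihda_mcmc(), seed = 1L, verbose = FALSE) {
  stopifnot(inherits(formula, "formula"), inherits(prior, "maihda_prior"),
            inherits(mcmc, "maihda_mcmc"))
  data <- as.data.frame(data)
  mf <- model.frame(formula, data, na.action = stats::na.fail)
  y <- as_binary_outcome(stats::model.response(mf))
  n <- length(y)
  if (n == 0) stop("no observations")
  if (all(y == 0L) || all(y == 1L)) {
    stop("degenerate outcome: both classes must be present")
  }
  trm <- terms(mf)
  X <- model.matrix(trm, mf)
  p <- ncol(X)

  # stratum assignment
  strata_name <- NULL
  if (inherits(strata, "maihda_strata")) {
    g <- strata$id
    map <- strata$map[, c("stratum", "n")]
    map$label <- apply(strata$map[, strata$vars, drop = FALSE], 1,
                       paste, collapse = " / ")
  } else if (is.character(strata) && length(strata) == 1) {
    if (!strata %in% names(data)) stop("strata column missing from data")
    strata_name <- strata
    gg <- factor(data[[strata]])
    g <- as.integer(gg)
    map <- data.frame(stratum = seq_len(nlevels(gg)),
                      n = as.integer(table(gg)), label = levels(gg))
  } else {
    gg <- factor(strata)
    if (length(gg) != n) stop("strata vector must match the number of rows")
    g <- as.integer(gg)
    map <- data.frame(stratum = seq_len(nlevels(gg)),
                      n = as.integer(table(gg)), label = levels(gg))
  }
  if (anyNA(g)) stop("missing stratum assignments")
  J <- nrow(map)

  # separation risk: dummy levels with no cases or no non-cases
  if (p > 1) {
    for (j in 2:p) {
      xj <- X[, j]
      if (all(xj %in% c(0, 1)) && sum(xj) > 0 &&
          (sum(y[xj == 1]) == 0 || sum((1 - y)[xj == 1]) == 0)) {
        warning(sprintf("fixed-effect level '%s' has zero cases in one class (separation risk)",
                        colnames(X)[j]))
      }
    }
  }

  n_keep <- length(seq.int(mcmc$burnin + 1L, mcmc$iterations, mcmc$thin))
  kappa <- y - 0.5
  B0inv <- diag(1 / prior$beta_sd^2, p)
  nu <- prior$sigma_df
  A <- prior$sigma_scale
  glev <- factor(g, levels = seq_len(J))

  run_chain <- function(chain) {
    set.seed((as.integer(seed) * 1009L + chain) %% .Machine$integer.max)
    beta <- rnorm(p, 0, 0.02)
    u <- numeric(J)
    sigma2 <- exp(runif(1, -0.4, 0.4))  # sigma_u init 1, jittered
    a <- 1
    out_beta <- matrix(NA_real_, n_keep, p)
    out_u <- matrix(NA_real_, n_keep, J)
    out_s2 <- numeric(n_keep)
    psum <- numeric(n)
    etasum <- numeric(n)
    k <- 0L
    for (it in seq_len(mcmc$iterations)) {
      eta <- drop(X %*% beta) + u[g]
      omega <- rpg_cpp(eta)
      # beta | omega, u  (conjugate multivariate normal)
      prec <- crossprod(X, X * omega) + B0inv
      R <- chol(prec)
      m <- crossprod(X, kappa - omega * u[g])
      mu_b <- backsolve(R, forwardsolve(t(R), m))
      beta <- drop(mu_b + backsolve(R, rnorm(p)))
      # u_j | omega, beta  (independent scalar normals)
      xb <- drop(X %*% beta)
      pr_u <- drop(rowsum(omega, glev)) + 1 / sigma2
      mu_u <- drop(rowsum(kappa - omega * xb, glev)) / pr_u
      u <- rnorm(J, mu_u, 1 / sqrt(pr_u))
      # sigma_u^2 | u  (half-t via inverse-gamma scale mixture)
      a <- 1 / rgamma(1, (nu + 1) / 2, rate = nu / sigma2 + 1 / A^2)
      sigma2 <- 1 / rgamma(1, (nu + J) / 2, rate = nu / a + sum(u^2) / 2)
      if (it > mcmc$burnin && (it - mcmc$burnin) %% mcmc$thin == 0L) {
        k <- k + 1L
        out_beta[k, ] <- beta
        out_u[k, ] <- u
        out_s2[k] <- sigma2
        eta_k <- xb + u[g]
        etasum <- etasum + eta_k
        psum <- psum + plogis(eta_k)
      }
    }
    if (verbose) message(sprintf("chain %d done (%d retained draws)", chain, k))
    list(beta = out_beta, u = out_u, sigma2 = out_s2,
         psum = psum, etasum = etasum)
  }

  chains <- lapply(seq_len(mcmc$chains), run_chain)

  draws <- list(
    beta = do.call(rbind, lapply(chains, `[[`, "beta")),
    u = do.call(rbind, lapply(chains, `[[`, "u")),
    sigma2 = unlist(lapply(chains, `[[`, "sigma2"))
  )
  colnames(draws$beta) <- colnames(X)
  chain_id <- rep(seq_len(mcmc$chains), each = n_keep)
  total <- n_keep * mcmc$chains
  p_hat <- Reduce(`+`, lapply(chains, `[[`, "psum")) / total
  linpred <- Reduce(`+`, lapply(chains, `[[`, "etasum")) / total

  mon <- cbind(draws$beta, sigma2_u = draws$sigma2)
  diag_df <- data.frame(
    parameter = colnames(mon),
    rhat = apply(mon, 2, split_rhat, chain = chain_id),
    ess_bulk = apply(mon, 2, ess_bulk, chain = chain_id),
    row.names = NULL
  )
  converged <- all(diag_df$rhat < 1.05, na.rm = TRUE)
  if (!converged) {
    warning("fit flagged non-converged: split R-hat above 1.05 for ",
            paste(diag_df$parameter[diag_df$rhat >= 1.05], collapse = ", "))
  }

  out <- list(
    call = match.call(), formula = formula, terms = trm,
    xlevels = stats::.getXlevels(trm, mf),
    y = y, n = n, J = J, g = g, strata_map = map,
    strata_name = strata_name, coef_names = colnames(X), X = X,
    draws = draws, chain = chain_id,
    p_hat = p_hat, linpred = linpred,
    prior = prior, mcmc = mcmc, seed = as.integer(seed),
    diagnostics = diag_df, converged = converged
  )
  class(out) <- "maihda_fit"
  out
}

#' Posterior median between-strata variance of a fit
#'
#' @param fit a `maihda_fit`.
#' @return posterior median of `sigma_u^2` (logit-squared scale).
#' @export
strata_variance <- function(fit) {
  stopifnot(inherits(fit, "maihda_fit"))
  median(fit$draws$sigma2)
}

#' Odds-ratio table from a MAIHDA fit
#'
#' `OR = exp(posterior median)` of each fixed-effect log-odds contrast with
#' an equal-tailed 95% interval; the intercept is reported on the odds
#' scale (baseline odds of the outcome at the reference category of every
#' covariate).
#'
#' @param fit a `maihda_fit`.
#' @param prob interval probability.
#' @return data frame with `term`, `or`, `lower`, `upper`, `significant`
#'   (interval excludes 1; `NA` for the intercept row).
#' @export
odds_ratio_table <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "maihda_fit"), prob > 0, prob < 1)
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  b <- fit$draws$beta
  est <- exp(apply(b, 2, median))
  lo <- exp(apply(b, 2, quantile, probs = qs[1]))
  hi <- exp(apply(b, 2, quantile, probs = qs[2]))
  sig <- lo > 1 | hi < 1
  sig[1] <- NA
  data.frame(term = colnames(b), or = unname(est), lower = unname(lo),
             upper = unname(hi), significant = unname(sig))
}

#' @export
print.maihda_fit <- function(x, ...) {
  v <- strata_variance(x)
  cat("Two-level Bayesian logistic MAIHDA model\n")
  cat("  formula:", deparse(x$formula), "\n")
  cat(sprintf("  %d individuals in %d intersectional strata\n", x$n, x$J))
  cat(sprintf("  strata variance (posterior median): %.3f  |  VPC: %.2f%%\n",
              v, vpc(v)))
  cat(sprintf("  %d retained draws (%d chains); %s\n",
              length(x$draws$sigma2), x$mcmc$chains,
              if (x$converged) "converged (all split R-hat < 1.05)"
              else "NOT converged (split R-hat >= 1.05)"))
  invisible(x)
}

#' @export
summary.maihda_fit <- function(object, ...) {
  out <- list(
    formula = object$formula, n = object$n, J = object$J,
    or_table = odds_ratio_table(object),
    strata_variance = strata_variance(object),
    vpc = vpc(strata_variance(object)),
    auc = auc_roc(object$y, object$p_hat),
    diagnostics = object$diagnostics,
    converged = object$converged
  )
  class(out) <- "summary.maihda_fit"
  out
}

#' @export
print.summary.maihda_fit <- function(x, digits = 2, ...) {
  cat("Two-level Bayesian logistic MAIHDA model\n")
  cat("  formula:", deparse(x$formula), "\n")
  cat(sprintf("  %d individuals in %d strata\n\n", x$n, x$J))
  ot <- x$or_table
  ot$or <- round(ot$or, digits)
  ot$lower <- round(ot$lower, digits)
  ot$upper <- round(ot$upper, digits)
  print(ot, row.names = FALSE)
  cat(sprintf("\n  strata variance %.3f | VPC %.2f%% | AUC-ROC %.2f%%\n",
              x$strata_variance, x$vpc, 100 * x$auc))
  cat(sprintf("  max split R-hat %.3f | min bulk ESS %.0f | %s\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess_bulk, na.rm = TRUE),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.maihda_fit <- function(object, ...) {
  apply(object$draws$beta, 2, median)
}

#' Posterior predictions from a MAIHDA fit
#'
#' Without `newdata`, returns the in-sample posterior-mean predicted
#' probability (or linear predictor), which includes each individual's
#' stratum effect `u_j` — the prediction used for the AUC-ROC. With
#' `newdata`, predictions use the posterior draws of the fixed effects
#' only (`u = 0`, i.e. an individual from an average stratum).
#'
#' @param object a `maihda_fit`.
#' @param newdata optional data frame of covariates.
#' @param type `"response"` (probability) or `"link"` (log-odds).
#' @param ... unused.
#' @export
predict.maihda_fit <- function(object, newdata = NULL,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(if (type == "response") object$p_hat else object$linpred)
  }
  tt <- stats::delete.response(object$terms)
  mf <- model.frame(tt, as.data.frame(newdata), xlev = object$xlevels)
  X <- model.matrix(tt, mf)
  eta <- X %*% t(object$draws$beta)          # n_new x draws
  if (type == "response") rowMeans(plogis(eta)) else rowMeans(eta)
}

#' @export
residuals.maihda_fit <- function(object, ...) {
  object$y - object$p_hat
}

#' Posterior predictive simulation of outcomes
#'
#' Draws binary outcome vectors from randomly selected retained posterior
#' draws (fixed effects and stratum effects of the fitted strata).
#'
#' @param object a `maihda_fit`.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with `nsim` columns of 0/1 outcomes.
#' @export
simulate.maihda_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n_draws <- length(object$draws$sigma2)
  idx <- sample.int(n_draws, nsim, replace = nsim > n_draws)
  sims <- vapply(idx, function(d) {
    eta <- drop(object$X %*% object$draws$beta[d, ]) +
      object$draws$u[d, object$g]
    rbinom(object$n, 1, plogis(eta))
  }, integer(object$n))
  sims <- as.data.frame(sims)
  names(sims) <- paste0("sim_", seq_len(nsim))
  sims
}

#' @export
plot.maihda_fit <- function(x, ...) {
  plot(stratum_effects(x), ...)
}

#' Persist the posterior of a fit to disk
#'
#' Writes the retained draws as a compressed columnar CSV (one column per
#' parameter, plus the chain index; stratum effects in a second file), the
#' fit metadata and convergence diagnostics as JSON, and per-chain trace
#' plots for the intercept and the between-strata variance as a PNG.
#'
#' @param fit a [maihda] fit.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisibly, the paths written.
#' @export
write_fit_artifacts <- function(fit, dir, prefix = "fit") {
  stopifnot(inherits(fit, "maihda_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, paste0(prefix, "_", f))

  con <- gzfile(p("draws.csv.gz"), "w")
  write.csv(data.frame(chain = fit$chain, fit$draws$beta,
                       sigma2_u = fit$draws$sigma2, check.names = FALSE),
            con, row.names = FALSE)
  close(con)
  con <- gzfile(p("draws_u.csv.gz"), "w")
  u <- as.data.frame(fit$draws$u)
  names(u) <- paste0("u_", fit$strata_map$stratum)
  write.csv(cbind(chain = fit$chain, u), con, row.names = FALSE)
  close(con)

  jsonlite::write_json(
    list(formula = deparse(fit$formula), n = fit$n, J = fit$J,
         seed = fit$seed, mcmc = unclass(fit$mcmc),
         prior = unclass(fit$prior), converged = fit$converged,
         diagnostics = fit$diagnostics),
    p("meta.json"), auto_unbox = TRUE, digits = NA)

  grDevices::png(p("trace.png"), width = 900, height = 600)
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit({graphics::par(old); grDevices::dev.off()}, add = TRUE)
  for (par_name in c("(Intercept)", "sigma2_u")) {
    vals <- if (par_name == "sigma2_u") fit$draws$sigma2
            else fit$draws$beta[, 1]
    plot(NA, xlim = c(1, sum(fit$chain == 1)), ylim = range(vals),
         xlab = "retained draw", ylab = par_name, main = par_name)
    for (ch in unique(fit$chain)) {
      graphics::lines(vals[fit$chain == ch], col = ch)
    }
  }
  invisible(c(p("draws.csv.gz"), p("draws_u.csv.gz"), p("meta.json"),
              p("trace.png")))
}

# split R-hat (Gelman et al.): each chain halved, variance-ratio statistic
split_rhat <- function(x, chain) {
  pieces <- split(x, chain)
  halves <- unlist(lapply(pieces, function(v) {
    h <- length(v) %/% 2
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# bulk effective sample size via per-chain autocorrelations, truncated at the
# first lag where the paired autocorrelation sum turns negative (Geyer)
ess_bulk <- function(x, chain) {
  pieces <- split(x, chain)
  n <- length(pieces[[1]])
  m <- length(pieces)
  if (n < 4) return(NA_real_)
  cmeans <- vapply(pieces, mean, 0)
  W <- mean(vapply(pieces, var, 0))
  B <- var(cmeans)
  varplus <- (n - 1) / n * W + B
  if (varplus == 0) return(NA_real_)
  max_lag <- min(n - 1, 200)
  rho <- numeric(max_lag)
  acfs <- lapply(pieces, function(v) {
    drop(stats::acf(v, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf)[-1] * var(v)
  })
  for (t in seq_len(max_lag)) {
    rho[t] <- 1 - (W - mean(vapply(acfs, `[`, 0, t))) / varplus
  }
  s <- 0
  t <- 1
  while (t + 1 <= max_lag) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  m * n / (1 + 2 * s)
}
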
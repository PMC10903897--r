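test_that("fit recovers intercept and fixed effect on a known cohort", {
  d <- toy_cohort(n = 3000, sigma_u = 0.4, seed = 41)
  f <- maihda(outcome ~ x1, d$data, strata = "stratum",
              mcmc = mcmc_quick(), seed = 1)
  b <- coef(f)
  expect_lt(abs(b["(Intercept)"] - (-1)), 0.3)
  expect_lt(abs(b["x1b"] - 0.7), 0.3)
  expect_true(all(f$draws$sigma2 > 0))
  expect_identical(ncol(f$draws$u), f$J)
  expect_true(all(f$p_hat > 0 & f$p_hat < 1))
  # retained draws = (iterations - burnin) / thin per chain
  expect_identical(length(f$draws$sigma2), 2L * (800L - 200L) %/% 2L)
})

test_that("same seed gives identical draws; row order changes nothing material", {
  cfg <- cohort_config(
    n = 2000,
    covariates = list(g = setNames(rep(0.05, 20), sprintf("s%02d", 1:20)),
                      x1 = c(a = 0.5, b = 0.5)),
    beta0 = -1, betas = list(x1 = c(b = 0.7)), sigma_u = 0.3,
    strata_vars = "g", seed = 42)
  d <- simulate_cohort(cfg)
  f1 <- maihda(outcome ~ x1, d$data, "stratum", mcmc = mcmc_quick(), seed = 9)
  f2 <- maihda(outcome ~ x1, d$data, "stratum", mcmc = mcmc_quick(), seed = 9)
  expect_identical(f1$draws, f2$draws)

  set.seed(5)
  perm <- sample.int(nrow(d$data))
  f3 <- maihda(outcome ~ x1, d$data[perm, ], "stratum",
               mcmc = mcmc_quick(), seed = 9)
  expect_lt(abs(median(f3$draws$beta[, 1]) - median(f1$draws$beta[, 1])), 0.1)
  expect_lt(abs(strata_variance(f3) - strata_variance(f1)), 0.1)
})

test_that("degenerate inputs raise the documented errors and warnings", {
  d <- toy_cohort(n = 300, seed = 43)
  dd <- d$data
  dd$outcome <- 0
  expect_error(maihda(outcome ~ x1, dd, "stratum", mcmc = mcmc_quick()),
               "degenerate outcome")
  expect_error(maihda(outcome ~ x1, d$data, "nonexistent", mcmc = mcmc_quick()),
               "strata column missing")
  # a level with zero cases triggers a separation-risk warning
  dd2 <- d$data
  dd2$outcome[dd2$x2 == "b"] <- 0
  expect_warning(
    maihda(outcome ~ x2, dd2, "stratum", mcmc = maihda_mcmc(100, 20, 2, 1),
           seed = 2),
    "separation risk")
  expect_error(maihda_mcmc(1000, 2000), "burnin < iterations")
  expect_error(maihda_mcmc(chains = 1), "chains >= 2")
})

test_that("posterior centres agree with an independent frequentist fit", {
  cfg <- cohort_config(
    n = 4000,
    covariates = list(g = setNames(rep(1 / 30, 30), sprintf("s%02d", 1:30)),
                      x1 = c(a = 0.5, b = 0.5)),
    beta0 = -1, betas = list(x1 = c(b = 0.7)), sigma_u = 0.5,
    strata_vars = "g", seed = 44)
  d <- simulate_cohort(cfg)
  f <- maihda(outcome ~ x1, d$data, "stratum",
              mcmc = maihda_mcmc(1500, 300, 2, 2), seed = 3)
  g <- lme4::glmer(outcome ~ x1 + (1 | stratum), data = d$data,
                   family = binomial())
  fe <- lme4::fixef(g)
  expect_lt(abs(coef(f)["(Intercept)"] - fe[1]), 0.2)
  expect_lt(abs(coef(f)["x1b"] - fe[2]), 0.2)
  s2_glmer <- unname(lme4::VarCorr(g)$stratum[1])
  expect_lt(abs(strata_variance(f) - s2_glmer), 0.25)
})

test_that("small strata are shrunk towards zero relative to raw deviations", {
  cfg <- cohort_config(
    n = 1500,
    covariates = list(g = setNames(rep(1 / 30, 30), sprintf("s%02d", 1:30))),
    beta0 = -1, sigma_u = 0.5, strata_vars = "g", seed = 45)
  d <- simulate_cohort(cfg)
  f <- maihda(outcome ~ 1, d$data, "stratum", mcmc = mcmc_quick(), seed = 4)
  eff <- stratum_effects(f)
  small <- eff$n <= 5
  if (!any(small)) small <- eff$n <= min(eff$n) + 1
  y <- d$data$outcome
  g <- d$data$stratum
  overall <- qlogis(mean(y))
  raw_dev <- abs(vapply(which(small), function(j) {
    yj <- y[g == eff$stratum[j]]
    qlogis((sum(yj) + 0.5) / (length(yj) + 1)) - overall
  }, 0))
  expect_lt(mean(abs(eff$estimate[small])), mean(raw_dev))
})

test_that("odds-ratio table matches a sort-based quantile oracle", {
  d <- toy_cohort(n = 1000, sigma_u = 0.3, seed = 46)
  f <- maihda(outcome ~ x1 + x2, d$data, "stratum", mcmc = mcmc_quick(),
              seed = 6)
  ot <- odds_ratio_table(f)
  for (k in seq_along(ot$term)) {
    draws <- f$draws$beta[, k]
    expect_equal(ot$or[k], exp(quantile_bruteforce(draws, 0.5)),
                 tolerance = 1e-12)
    expect_equal(ot$lower[k], exp(quantile_bruteforce(draws, 0.025)),
                 tolerance = 1e-12)
    expect_equal(ot$upper[k], exp(quantile_bruteforce(draws, 0.975)),
                 tolerance = 1e-12)
  }
  # closed-form degenerate cases through a handcrafted fit object
  fake <- f
  fake$draws$beta <- matrix(0, 100, 2,
                            dimnames = list(NULL, c("(Intercept)", "x1b")))
  ot0 <- odds_ratio_table(fake)
  expect_equal(ot0$or, c(1, 1))
  expect_equal(ot0$lower, c(1, 1))
  fake$draws$beta[, 2] <- rnorm(100, log(2), 1e-8)
  expect_equal(odds_ratio_table(fake)$or[2], 2, tolerance = 1e-4)
})

test_that("predict, residuals and simulate are coherent with the fit", {
  d <- toy_cohort(n = 800, sigma_u = 0.3, seed = 47)
  f <- maihda(outcome ~ x1, d$data, "stratum", mcmc = mcmc_quick(), seed = 7)
  p <- predict(f)
  expect_identical(p, f$p_hat)
  expect_equal(predict(f, type = "link"), f$linpred)
  expect_equal(residuals(f), f$y - p)
  # AUC of in-sample predictions beats chance on data with real structure
  expect_gt(auc_roc(f$y, p), 0.5)
  # newdata predictions: fixed effects only, reference level lower risk here
  nd <- data.frame(x1 = c("a", "b"), x2 = "a")
  pn <- predict(f, newdata = nd)
  expect_length(pn, 2)
  expect_lt(pn[1], pn[2])
  sims <- simulate(f, nsim = 3, seed = 8)
  expect_identical(dim(sims), c(800L, 3L))
  expect_true(all(unlist(sims) %in% 0:1))
  # posterior predictive prevalence close to observed
  expect_lt(abs(mean(unlist(sims)) - mean(f$y)), 0.05)
})

test_that("fit artifacts persist draws, metadata and traces", {
  d <- toy_cohort(n = 400, sigma_u = 0.3, seed = 49)
  f <- maihda(outcome ~ 1, d$data, "stratum",
              mcmc = maihda_mcmc(200, 50, 2, 1), seed = 11)
  dir <- file.path(tempdir(), "maihda-fit-art")
  unlink(dir, recursive = TRUE)
  paths <- write_fit_artifacts(f, dir)
  expect_true(all(file.exists(paths)))
  draws <- read.csv(gzfile(file.path(dir, "fit_draws.csv.gz")),
                    check.names = FALSE)
  expect_identical(nrow(draws), length(f$draws$sigma2))
  expect_equal(draws$sigma2_u, f$draws$sigma2)
  meta <- jsonlite::read_json(file.path(dir, "fit_meta.json"))
  expect_equal(meta$J, f$J)
})

test_that("summary and print surface the discriminatory-accuracy quantities", {
  d <- toy_cohort(n = 600, sigma_u = 0.3, seed = 48)
  f <- maihda(outcome ~ x1, d$data, "stratum", mcmc = mcmc_quick(), seed = 10)
  s <- summary(f)
  expect_s3_class(s, "summary.maihda_fit")
  expect_equal(s$vpc, vpc(strata_variance(f)))
  expect_output(print(s), "VPC")
  expect_output(print(f), "intersectional strata")
  expect_identical(nrow(s$diagnostics), ncol(f$draws$beta) + 1L)
})
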
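# Independent oracles used across the suite. Each is a deliberately naive
# implementation kept separate from the package's code paths.

# AUC by brute force over all (positive, negative) pairs, ties 1/2
auc_bruteforce <- function(y, p) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# group rows into strata by nested looping over observed combinations,
# IDs in lexicographic order of the level combinations
group_bruteforce <- function(d, vars) {
  keys <- apply(d[, vars, drop = FALSE], 1, paste, collapse = "\r")
  lev <- lapply(vars, function(v) sort(unique(as.character(d[[v]]))))
  combos <- character()
  add <- function(prefix, depth) {
    if (depth > length(vars)) {
      combos <<- c(combos, paste(prefix, collapse = "\r"))
      return(invisible())
    }
    for (l in lev[[depth]]) add(c(prefix, l), depth + 1)
  }
  add(character(), 1)
  combos <- combos[combos %in% keys]   # observed only
  list(id = match(keys, combos), J = length(combos))
}

# sort-based equal-tailed quantile (type-7 interpolation done longhand)
quantile_bruteforce <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# small cohort with 20 strata and two binary covariates used by fit tests
toy_cohort <- function(n = 1500, sigma_u = 0.5, seed = 99, beta0 = -1) {
  cfg <- cohort_config(
    n = n,
    covariates = list(g = setNames(rep(0.05, 20), sprintf("s%02d", 1:20)),
                      x1 = c(a = 0.5, b = 0.5), x2 = c(a = 0.6, b = 0.4)),
    beta0 = beta0, betas = list(x1 = c(b = 0.7)), sigma_u = sigma_u,
    strata_vars = "g", seed = seed)
  simulate_cohort(cfg)
}

# reduced MCMC settings for quick unit-level fits
mcmc_quick <- function() maihda_mcmc(800, 200, 2, 2)
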
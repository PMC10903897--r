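#' Univariable screening of candidate strata-defining variables
#'
#' For each candidate, tests the association with the binary outcome by a
#' likelihood-ratio test of the univariable logistic regression
#' `outcome ~ candidate` against the intercept-only model (default), or by
#' a Pearson chi-square test of the contingency table. A candidate is
#' selected when `p < alpha` (strict: a p-value exactly equal to `alpha` is
#' not selected). Candidates with a single observed level are excluded with
#' a warning; quasi-separated candidates keep their LR-test p-value and a
#' separation warning is raised.
#'
#' @param data data frame of complete cases.
#' @param outcome binary outcome column name.
#' @param candidates character vector of categorical candidate columns.
#' @param alpha selection level.
#' @param test `"lrt"` (default) or `"chisq"`.
#' @return data frame of class `maihda_screen` with columns `variable`,
#'   `statistic`, `df`, `p_value`, `selected`.
#' @export
screen_covariates <- function(data, outcome, candidates, alpha = 0.05,
                              test = c("lrt", "chisq")) {
  test <- match.arg(test)
  data <- as.data.frame(data)
  stopifnot(outcome %in% names(data), all(candidates %in% names(data)),
            alpha > 0, alpha < 1)
  y <- as_binary_outcome(data[[outcome]])
  if (anyNA(y)) stop("missing outcome values: apply complete_case_filter first")
  rows <- lapply(candidates, function(v) {
    x <- factor(data[[v]])
    if (anyNA(x)) stop(sprintf("missing values in candidate '%s'", v))
    x <- droplevels(x)
    if (nlevels(x) < 2) {
      warning(sprintf("candidate '%s' has a single observed level; excluded", v))
      return(NULL)
    }
    if (test == "lrt") {
      sep <- FALSE
      fit <- withCallingHandlers(
        glm(y ~ x, family = binomial()),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                    conditionMessage(w))) {
            sep <<- TRUE
            invokeRestart("muffleWarning")
          }
        })
      if (any(fit$fitted.values < 1e-6 | fit$fitted.values > 1 - 1e-6)) {
        sep <- TRUE
      }
      stat <- fit$null.deviance - fit$deviance
      df <- nlevels(x) - 1L
      p <- pchisq(stat, df, lower.tail = FALSE)
      if (sep) {
        warning(sprintf(
          "possible separation for candidate '%s'; LR-test p-value reported", v))
      }
    } else {
      ct <- suppressWarnings(chisq.test(table(x, y), correct = FALSE))
      stat <- unname(ct$statistic)
      df <- unname(ct$parameter)
      p <- ct$p.value
    }
    data.frame(variable = v, statistic = stat, df = df, p_value = p,
               selected = p < alpha)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variable = character(), statistic = numeric(),
                      df = integer(), p_value = numeric(),
                      selected = logical())
  }
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("maihda_screen", "data.frame")
  out
}

#' Cramer's V association between two categorical variables
#'
#' `sqrt(chi2 / (n * (min(r, c) - 1)))` with `chi2` the uncorrected Pearson
#' statistic of the r-by-c contingency table. Symmetric and invariant under
#' relabelling. If either vector is constant, V is defined as 0 with a
#' warning.
#'
#' @param x,y equal-length vectors with no missing values.
#' @return V in `[0, 1]`.
#' @examples
#' cramers_v(rep(0:1, each = 40), rep(c(0, 1, 1, 0), times = c(30, 10, 30, 10)))
#' @export
cramers_v <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  tab <- table(x, y)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warning("constant variable: Cramer's V defined as 0")
    return(0)
  }
  chi2 <- unname(suppressWarnings(chisq.test(tab, correct = FALSE))$statistic)
  sqrt(chi2 / (sum(tab) * (min(dim(tab)) - 1)))
}

#' Resolve collinear strata-defining variables
#'
#' Computes pairwise Cramer's V among the screened-in variables; when a
#' pair exceeds `threshold`, warns and keeps the variable with the smaller
#' screening p-value.
#'
#' @param data data frame.
#' @param screen result of [screen_covariates()].
#' @param threshold Cramer's V above which a pair is flagged.
#' @return character vector of retained variable names (screening order).
#' @export
resolve_collinearity <- function(data, screen, threshold = 0.5) {
  vars <- screen$variable[screen$selected]
  if (length(vars) < 2) return(vars)
  p <- setNames(screen$p_value, screen$variable)
  drop <- character()
  pairs <- utils::combn(vars, 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    if (a %in% drop || b %in% drop) next
    v <- cramers_v(data[[a]], data[[b]])
    if (v > threshold) {
      loser <- if (p[a] <= p[b]) b else a
      warning(sprintf(
        "Cramer's V between '%s' and '%s' is %.2f (> %.2f); dropping '%s'",
        a, b, v, threshold, loser))
      drop <- c(drop, loser)
    }
  }
  setdiff(vars, drop)
}

#' Cross-classify individuals into intersectional strata
#'
#' Strata are the observed combinations of the selected variables only
#' (empty combinations are not represented). Integer IDs are assigned in
#' lexicographic order of the level combinations, first variable varying
#' slowest.
#'
#' @param data data frame with complete values in `vars`.
#' @param vars non-empty character vector of strata-defining columns.
#' @return list of class `maihda_strata`: `map` (data frame with `stratum`,
#'   one column per defining variable, and `n`), `id` (integer stratum ID
#'   per row of `data`), `vars`.
#' @export
build_strata <- function(data, vars) {
  data <- as.data.frame(data)
  if (length(vars) == 0) {
    stop(paste("no strata-defining variables: nothing passed screening;",
               "supply a variable list explicitly to force a specification"))
  }
  stopifnot(all(vars %in% names(data)))
  cols <- lapply(vars, function(v) {
    x <- data[[v]]
    if (anyNA(x)) stop(sprintf("missing values in strata variable '%s'", v))
    if (!is.factor(x)) x <- factor(x)
    droplevels(x)
  })
  names(cols) <- vars
  # observed combinations only, in lexicographic order (first variable slowest)
  combo <- unique(as.data.frame(cols))
  combo <- combo[do.call(order, combo), , drop = FALSE]
  rownames(combo) <- NULL
  row_key <- do.call(paste, c(cols, sep = "\r"))
  combo_key <- do.call(paste, c(as.list(combo), sep = "\r"))
  id <- match(row_key, combo_key)
  counts <- tabulate(id, nbins = nrow(combo))
  map <- cbind(data.frame(stratum = seq_len(nrow(combo))), combo,
               data.frame(n = counts))
  out <- list(map = map, id = id, vars = vars)
  class(out) <- "maihda_strata"
  out
}

#' @export
print.maihda_strata <- function(x, ...) {
  s <- strata_summary(x)
  cat(sprintf("Intersectional strata over %s\n", paste(x$vars, collapse = " x ")))
  cat(sprintf("  %d strata, %d individuals; counts min/median/max = %d/%g/%d\n",
              s$J, s$n, s$min, s$median, s$max))
  cat(sprintf("  %d (%.1f%%) strata with 5 or more members\n",
              s$n_ge5, s$pct_ge5))
  invisible(x)
}

#' Summarise a stratum map
#'
#' @param strata a `maihda_strata` object from [build_strata()].
#' @return list with `J` (number of strata), `n` (individuals), `min`,
#'   `median`, `max` member counts, `n_ge5` and `pct_ge5` (strata with at
#'   least five members).
#' @export
strata_summary <- function(strata) {
  stopifnot(inherits(strata, "maihda_strata"))
  cnt <- strata$map$n
  list(J = nrow(strata$map), n = sum(cnt), min = min(cnt),
       median = median(cnt), max = max(cnt),
       n_ge5 = sum(cnt >= 5), pct_ge5 = pct(sum(cnt >= 5), length(cnt)))
}
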
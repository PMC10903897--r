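#' Variance partitioning coefficient for a two-level logistic model
#'
#' Share of total latent-scale variance attributable to the intersectional
#' strata, as a percentage: `100 * sigma2_u / (sigma2_u + 3.29)`. The
#' level-1 residual variance of the latent logistic formulation is fixed at
#' 3.29 (pi^2 / 3 to two decimals, the convention used when reporting VPC
#' for multilevel logistic models).
#'
#' @param sigma2_u between-strata variance on the logit scale (a non-negative
#'   number), or a fitted model from [maihda()], in which case its posterior median
#'   strata variance is used.
#' @return VPC in percent, in `[0, 100)`.
#' @seealso [pcv()], [auc_roc()], [interpret_da()]
#' @examples
#' vpc(0.36)  # 9.86
#' vpc(0)     # 0
#' @export
vpc <- function(sigma2_u) {
  if (inherits(sigma2_u, "maihda_fit")) sigma2_u <- strata_variance(sigma2_u)
  stopifnot(is.numeric(sigma2_u))
  if (any(sigma2_u < 0)) stop("between-strata variance must be non-negative")
  100 * sigma2_u / (sigma2_u + 3.29)
}

#' Proportional change in variance relative to the null model
#'
#' `100 * (var_model1 - var_modelk) / var_model1`: the percentage of the
#' null (intercept-only) model's between-strata variance explained once
#' fixed effects are added. Values near 100% mean the strata differences
#' are accounted for by additive main effects; the unexplained remainder is
#' read as intersectional (interaction) effects. Can be negative when the
#' variance increases.
#'
#' @param var_model1 between-strata variance of the null model (> 0).
#' @param var_modelk between-strata variance of the adjusted model (>= 0).
#' @return PCV in percent (<= 100).
#' @examples
#' pcv(0.41, 0.32)
#' @export
pcv <- function(var_model1, var_modelk) {
  stopifnot(is.numeric(var_model1), is.numeric(var_modelk),
            all(var_modelk >= 0))
  if (any(var_model1 <= 0)) {
    stop("PCV undefined: null-model between-strata variance must be positive")
  }
  100 * (var_model1 - var_modelk) / var_model1
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen case has a higher predicted
#' probability than a randomly chosen non-case, ties counted 1/2. Computed
#' from midranks, which is algebraically the normalised Mann-Whitney U
#' statistic, so the result is invariant to strictly monotone transforms of
#' `p_hat`.
#'
#' @param y binary outcome (0/1, logical, or two-level factor where the
#'   second level is the case).
#' @param p_hat numeric predictions (any monotone score).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_roc(c(0, 0, 1, 1), c(0.2, 0.8, 0.4, 0.9))  # 0.75
#' @export
auc_roc <- function(y, p_hat) {
  y <- as_binary_outcome(y)
  if (length(y) != length(p_hat)) stop("y and p_hat must have equal length")
  if (anyNA(y) || anyNA(p_hat)) stop("missing values in y or p_hat")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both outcome classes must be present")
  }
  r <- rank(p_hat)                       # midranks give 1/2 credit to ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Qualitative discriminatory-accuracy labels
#'
#' Labels the VPC as `"acceptable"` when strictly greater than 5% (the
#' conventional threshold for the strata classification carrying useful
#' discriminatory information) and bands the AUC as poor (< 0.6), weak
#' (0.6 to < 0.7), good (0.7 to < 0.8) or excellent (>= 0.8).
#'
#' @param vpc_percent VPC in percent.
#' @param auc AUC as a fraction in `[0, 1]` (values > 1 are taken as percent
#'   and divided by 100).
#' @param vpc_threshold acceptability cutpoint for the VPC, percent.
#' @param auc_breaks increasing internal band edges for the AUC.
#' @return list with elements `vpc_label` and `auc_label`.
#' @examples
#' interpret_da(9.0, 0.766)
#' @export
interpret_da <- function(vpc_percent, auc, vpc_threshold = 5,
                         auc_breaks = c(0.6, 0.7, 0.8)) {
  stopifnot(length(auc_breaks) == 3, !is.unsorted(auc_breaks))
  if (auc > 1) auc <- auc / 100
  stopifnot(vpc_percent >= 0, vpc_percent <= 100, auc >= 0, auc <= 1)
  vpc_label <- if (vpc_percent > vpc_threshold) "acceptable" else "low"
  auc_label <- c("poor", "weak", "good", "excellent")[
    findInterval(auc, auc_breaks) + 1L]
  list(vpc_label = vpc_label, auc_label = auc_label)
}

#' Discriminatory-accuracy report across a model sequence
#'
#' Tabulates, per fitted model, the posterior-median between-strata
#' variance, VPC, PCV relative to the first (null) model, in-sample
#' AUC-ROC from the posterior-mean predicted probabilities (stratum
#' effects included), and the strata / individual counts.
#'
#' @param fits named list of [maihda()] fits; the first is treated as
#'   the null model for PCV.
#' @return data frame of class `maihda_da_report` with one row per model.
#' @export
da_report <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1,
            all(vapply(fits, inherits, TRUE, "maihda_fit")))
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste("Model", seq_along(fits))
  }
  v <- vapply(fits, strata_variance, 0)
  out <- data.frame(
    model = names(fits),
    strata_variance = v,
    vpc = vpc(v),
    pcv = c(NA_real_, if (length(v) > 1) pcv(v[1], v[-1])),
    auc_roc = vapply(fits, function(f) auc_roc(f$y, f$p_hat), 0),
    strata_n = vapply(fits, function(f) f$J, 0L),
    individual_n = vapply(fits, function(f) f$n, 0L),
    row.names = NULL
  )
  class(out) <- c("maihda_da_report", "data.frame")
  out
}

#' @export
print.maihda_da_report <- function(x, digits = 2, ...) {
  cat("Discriminatory accuracy (VPC / PCV / AUC-ROC)\n")
  y <- data.frame(
    model = x$model,
    `strata var` = round(x$strata_variance, digits),
    `VPC %` = round(x$vpc, digits),
    `PCV %` = round(x$pcv, digits),
    `AUC-ROC %` = round(100 * x$auc_roc, digits),
    `strata N` = x$strata_n,
    `N` = x$individual_n,
    check.names = FALSE
  )
  print(y, row.names = FALSE, ...)
  invisible(x)
}

# Coerce the accepted binary-outcome encodings to integer 0/1.
as_binary_outcome <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("outcome factor must have exactly two levels")
    return(as.integer(y == levels(y)[2]))
  }
  if (is.logical(y)) return(as.integer(y))
  if (is.character(y)) return(as_binary_outcome(factor(y)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1) | is.na(y))) {
    stop("numeric outcome must be coded 0/1")
  }
  as.integer(y)
}
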
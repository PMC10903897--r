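#' Asset-based wealth index by principal components
#'
#' First principal component of the standardised asset-indicator matrix
#' (PCA on the correlation matrix, the standard choice for binary asset
#' indicators with unequal variances). The component is sign-oriented so
#' that owning more assets increases the score. Households are cut into
#' quintiles at the 20/40/60/80th percentiles of the score and the
#' quintiles collapsed into tertile labels: quintiles 1-2 are `poor`,
#' 3 is `middle`, 4-5 are `rich`. Values falling exactly on a percentile
#' cutpoint go to the lower category.
#'
#' @param assets data frame or matrix of numeric (typically 0/1) asset
#'   indicator columns, one row per household. Constant columns are dropped
#'   with a warning.
#' @param tertile_map integer vector of length 5 mapping quintile (poorest
#'   = 1) to tertile index 1..3 (`poor`, `middle`, `rich`).
#' @return data frame with columns `pc1_score`, `quintile` (1 = poorest),
#'   `tertile` (factor rich/middle/poor with `rich` as reference).
#' @examples
#' set.seed(1)
#' a <- data.frame(radio = rbinom(50, 1, 0.5), tv = rbinom(50, 1, 0.3),
#'                 bike = rbinom(50, 1, 0.4))
#' head(wealth_index(a))
#' @export
wealth_index <- function(assets, tertile_map = c(1L, 1L, 2L, 3L, 3L)) {
  assets <- as.data.frame(assets)
  if (!all(vapply(assets, is.numeric, TRUE))) {
    stop("asset indicators must be numeric (use 0/1 coding)")
  }
  x <- as.matrix(assets)
  if (anyNA(x)) stop("missing values in asset indicators")
  const <- apply(x, 2, function(col) var(col) == 0)
  if (all(const)) stop("degenerate asset matrix: all indicator columns constant")
  if (any(const)) {
    warning(sprintf("dropping constant asset column(s): %s",
                    paste(colnames(x)[const], collapse = ", ")))
    x <- x[, !const, drop = FALSE]
  }
  if (nrow(x) < 3) stop("need at least 3 households")
  if (nrow(x) < ncol(x)) stop("fewer households than asset indicators")
  if (all(duplicated(x)[-1])) stop("degenerate asset matrix: all households identical")
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  score <- p$x[, 1]
  # orient: more assets => higher score
  if (cor(score, rowSums(scale(x))) < 0) score <- -score
  br <- quantile(score, probs = seq(0, 1, 0.2), names = FALSE)
  quintile <- cut_lower(score, br)
  stopifnot(length(tertile_map) == 5, all(tertile_map %in% 1:3))
  tert <- c("poor", "middle", "rich")[tertile_map[quintile]]
  data.frame(
    pc1_score = as.numeric(score),
    quintile = quintile,
    tertile = factor(tert, levels = c("rich", "middle", "poor"))
  )
}

# interval index with values exactly at an internal cutpoint assigned to the
# lower category; breaks are the 0/20/.../100th percentiles (or similar)
cut_lower <- function(x, breaks) {
  idx <- findInterval(x, breaks, left.open = TRUE, rightmost.closed = FALSE)
  idx[x <= breaks[1]] <- 1L
  pmin(idx, length(breaks) - 1L)
}

#' Catastrophic health expenditure at a capacity-to-pay threshold
#'
#' Flags households whose out-of-pocket health payments equal or exceed
#' `threshold` (default 40%) of their capacity to pay, following the
#' WHO/Xu procedure: household equivalent size is `household_size^beta`
#' (default beta = 0.56); the subsistence poverty line is the (optionally
#' weighted) mean equivalised food expenditure among households whose food
#' share of total expenditure lies in the 45th-55th percentile band;
#' subsistence spending is the line times equivalent size; capacity to pay
#' is total expenditure minus subsistence spending when reported food
#' spending is at or above subsistence, otherwise total minus food.
#'
#' @param records data frame with columns `total_expenditure`,
#'   `food_expenditure`, `oop_health`, `household_size`.
#' @param threshold CHE threshold as a fraction of capacity to pay;
#'   the comparison is inclusive (`>=`).
#' @param eq_scale equivalence-scale exponent.
#' @param band food-share percentile band (fractions) used to estimate the
#'   subsistence line; widened symmetrically (with a message) if empty.
#' @param weights optional household weights for the subsistence line.
#' @return the input data frame with derived columns `equivalent_size`,
#'   `food_share`, `subsistence_spending`, `capacity_to_pay` and `che_flag`
#'   (factor no/yes; `NA` for excluded records). Households with
#'   non-positive capacity to pay are excluded from flagging; their count is
#'   in `attr(, "n_unusable")`, and the subsistence line in
#'   `attr(, "subsistence_line")`.
#' @export
compute_che <- function(records, threshold = 0.40, eq_scale = 0.56,
                        band = c(0.45, 0.55), weights = NULL) {
  records <- as.data.frame(records)
  need <- c("total_expenditure", "food_expenditure", "oop_health",
            "household_size")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("missing expenditure column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) < 1) stop("need at least one household record")
  tot <- records$total_expenditure
  food <- records$food_expenditure
  oop <- records$oop_health
  hh <- records$household_size
  if (anyNA(c(tot, food, oop, hh))) stop("missing values in expenditure fields")
  if (any(tot <= 0) || any(food < 0) || any(oop < 0)) {
    stop("expenditures must be positive (total) / non-negative (food, OOP)")
  }
  if (any(food > tot)) stop("food expenditure exceeds total expenditure")
  if (any(hh < 1)) stop("household size must be >= 1")
  if (is.null(weights)) weights <- rep(1, length(tot))

  eqsize <- hh^eq_scale
  food_share <- food / tot
  eq_food <- food / eqsize

  # subsistence line from the mid-food-share band, widening if empty
  b <- band
  repeat {
    qs <- quantile(food_share, probs = b, names = FALSE)
    in_band <- food_share >= qs[1] & food_share <= qs[2]
    if (any(in_band)) break
    b <- c(max(0, b[1] - 0.05), min(1, b[2] + 0.05))
    message(sprintf("empty food-share band; widened to [%.0f%%, %.0f%%]",
                    100 * b[1], 100 * b[2]))
  }
  line <- sum(weights[in_band] * eq_food[in_band]) / sum(weights[in_band])

  subsistence <- line * eqsize
  ctp <- ifelse(food >= subsistence, tot - subsistence, tot - food)

  usable <- ctp > 0
  n_unusable <- sum(!usable)
  if (n_unusable > 0) {
    message(sprintf("%d household(s) with non-positive capacity to pay excluded",
                    n_unusable))
  }
  flag <- rep(NA_character_, length(ctp))
  flag[usable] <- ifelse(oop[usable] / ctp[usable] >= threshold, "yes", "no")

  records$equivalent_size <- eqsize
  records$food_share <- food_share
  records$subsistence_spending <- subsistence
  records$capacity_to_pay <- ctp
  records$che_flag <- factor(flag, levels = c("no", "yes"))
  attr(records, "subsistence_line") <- line
  attr(records, "n_unusable") <- n_unusable
  records
}

#' Recode raw survey fields to the analysis categories
#'
#' Maps raw units to the categorical analysis variables: child age in
#' months to `1 year and less` (under 24 months) vs `2-5 years`; mother age
#' in years to `18 years and less` (the age-of-consent boundary separating
#' child from adult mothers) vs `19-49 years`; head-of-household age to
#' `17-24` / `25-34` / `35 and over`; length of stay in years to
#' `new migrants` (2 years and less), `old migrants` (more than 2 years) or
#' `missing/not applicable`. Remaining categorical fields are validated
#' against their documented level sets and converted to factors with the
#' documented reference level first. Rows with out-of-range values are kept
#' but flagged in `attr(, "invalid_rows")`.
#'
#' @param raw data frame with any of the columns `child_age_months`,
#'   `mother_age_years`, `head_age_years`, `stay_years`, plus categorical
#'   fields among those listed by [analysis_levels()].
#' @return data frame with recoded columns (`child_age`, `mother_age`,
#'   `head_age`, `length_of_stay` replace their raw counterparts).
#' @export
recode_variables <- function(raw) {
  raw <- as.data.frame(raw)
  out <- raw
  invalid <- rep(FALSE, nrow(raw))

  if (!is.null(raw$child_age_months)) {
    m <- raw$child_age_months
    bad <- !is.na(m) & (m < 0 | m > 71)
    invalid <- invalid | bad
    out$child_age <- factor(
      ifelse(is.na(m) | bad, NA, ifelse(m < 24, "1 year and less", "2-5 years")),
      levels = analysis_levels()$child_age)
    out$child_age_months <- NULL
  }
  if (!is.null(raw$mother_age_years)) {
    a <- raw$mother_age_years
    bad <- !is.na(a) & (a < 10 | a > 49)
    invalid <- invalid | bad
    out$mother_age <- factor(
      ifelse(is.na(a) | bad, NA,
             ifelse(a <= 18, "18 years and less", "19-49 years")),
      levels = analysis_levels()$mother_age)
    out$mother_age_years <- NULL
  }
  if (!is.null(raw$head_age_years)) {
    a <- raw$head_age_years
    bad <- !is.na(a) & a < 17
    invalid <- invalid | bad
    out$head_age <- factor(
      ifelse(is.na(a) | bad, NA,
             ifelse(a <= 24, "17-24", ifelse(a <= 34, "25-34", "35 and over"))),
      levels = analysis_levels()$head_age)
    out$head_age_years <- NULL
  }
  if (!is.null(raw$stay_years)) {
    s <- raw$stay_years
    bad <- !is.na(s) & s < 0
    invalid <- invalid | bad
    lev <- ifelse(is.na(s), "missing/not applicable",
                  ifelse(bad, NA, ifelse(s <= 2, "new migrants", "old migrants")))
    out$length_of_stay <- factor(lev, levels = analysis_levels()$length_of_stay)
    out$stay_years <- NULL
  }

  for (v in intersect(names(analysis_levels()), names(out))) {
    lv <- analysis_levels()[[v]]
    if (!is.factor(out[[v]])) {
      val <- as.character(out[[v]])
      bad <- !is.na(val) & !(val %in% lv)
      invalid <- invalid | bad
      val[bad] <- NA
      out[[v]] <- factor(val, levels = lv)
    }
  }
  attr(out, "invalid_rows") <- which(invalid)
  if (any(invalid)) {
    warning(sprintf("%d row(s) with out-of-range values flagged invalid",
                    sum(invalid)))
  }
  out
}

#' Documented analysis category levels (reference level first)
#'
#' Level sets for the categorical analysis variables; the first level of
#' each is the modelling reference (e.g. Kamba, rich, new migrants,
#' female child).
#'
#' @return named list of character level vectors.
#' @export
analysis_levels <- function() {
  list(
    child_age = c("1 year and less", "2-5 years"),
    child_sex = c("female", "male"),
    mother_age = c("18 years and less", "19-49 years"),
    mother_education = c("primary", "post primary", "none"),
    head_sex = c("female", "male"),
    head_age = c("17-24", "25-34", "35 and over"),
    head_ethnicity = c("Kamba", "Kikuyu", "Luhya", "Luo", "other"),
    head_education = c("none", "educated", "don't know/not applicable"),
    wealth = c("rich", "middle", "poor"),
    length_of_stay = c("new migrants", "old migrants", "missing/not applicable"),
    religion = c("catholic", "protestant", "other"),
    tenure = c("no rent paid", "pays rent"),
    food_security = c("enough", "not enough"),
    health_insurance = c("no", "yes"),
    income_activity = c("employed", "own business", "missing/not applicable"),
    che = c("no", "yes")
  )
}

#' Complete-case filter with drop accounting
#'
#' Drops rows with a missing outcome first, then rows missing any listed
#' covariate, and reports both counts in the survey-report style
#' ("170 (8.2%) were due to missing outcomes ...").
#'
#' @param data cohort data frame.
#' @param outcome outcome column name.
#' @param covariates character vector of covariate column names.
#' @return list of class `maihda_drop_report` with elements `data` (the
#'   filtered data frame), `n_input`, `n_dropped_outcome`,
#'   `n_dropped_covariate`, `n_kept`.
#' @export
complete_case_filter <- function(data, outcome, covariates) {
  data <- as.data.frame(data)
  stopifnot(outcome %in% names(data), all(covariates %in% names(data)))
  n0 <- nrow(data)
  miss_y <- is.na(data[[outcome]])
  d1 <- data[!miss_y, , drop = FALSE]
  miss_x <- Reduce(`|`, lapply(covariates, function(v) is.na(d1[[v]])),
                   accumulate = FALSE, init = rep(FALSE, nrow(d1)))
  kept <- d1[!miss_x, , drop = FALSE]
  if (nrow(kept) == 0) stop("empty analysis set: all rows dropped")
  out <- list(
    data = kept,
    outcome = outcome,
    n_input = n0,
    n_dropped_outcome = sum(miss_y),
    n_dropped_covariate = sum(miss_x),
    n_kept = nrow(kept)
  )
  class(out) <- "maihda_drop_report"
  out
}

#' @export
print.maihda_drop_report <- function(x, ...) {
  nd <- x$n_dropped_outcome + x$n_dropped_covariate
  cat(sprintf(
    "Complete-case analysis sample for %s: %s records after %s were dropped;\n",
    x$outcome, format(x$n_kept, big.mark = ","),
    format_count_pct(nd, x$n_input)))
  cat(sprintf("of which %s were due to missing outcomes and %s had missing\n",
              format_count_pct(x$n_dropped_outcome, x$n_input),
              format_count_pct(x$n_dropped_covariate, x$n_input)))
  cat("values in variables considered for intersectional strata.\n")
  invisible(x)
}
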
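#' Run the full intersectional MAIHDA analysis pipeline
#'
#' Orchestrates, per outcome: input (synthetic cohort or CSV) -> optional
#' sensitivity subsetting -> complete-case filter with drop accounting ->
#' univariable screening -> Cramer's V collinearity resolution ->
#' intersectional strata -> the three-model MAIHDA sequence (null, strata
#' main effects, all covariates) -> discriminatory-accuracy report ->
#' ranked stratum effects -> combined results table, with a machine-readable
#' JSON summary and a manifest recording the configuration hash and seed.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   `seed` (integer, required); `input` (`mode = "synthetic"` with
#'   `preset`/`n`/`sigma_u`, or `mode = "csv"` with `path`); `outcomes`
#'   (character); `candidates` (character; default: all analysis covariates
#'   present in the data); `alpha` (default 0.05); `v_threshold` (default
#'   0.5); `mcmc_profile` (`"test"` or `"paper"`, default `"test"`) or a
#'   full `mcmc` list; `prior` list; `sensitivity`
#'   (`"exclude-dk-education"` to drop the "don't know/not applicable"
#'   head-education level before analysis).
#' @param output_dir optional directory; when given, all artifacts (CSV
#'   tables, JSON reports, caterpillar PNGs, manifest) are written under it.
#' @return list of class `maihda_run` with one element per outcome
#'   (`drop_report`, `screen`, `strata`, `fits`, `da`, `effects`, `table1`,
#'   `summary`) plus `manifest`.
#' @export
run_maihda_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$seed))
  seed <- as.integer(config$seed)
  alpha <- config$alpha %||% 0.05
  v_threshold <- config$v_threshold %||% 0.5
  prior <- do.call(maihda_prior, config$prior %||% list())
  mcmc <- if (!is.null(config[["mcmc"]])) do.call(maihda_mcmc, config[["mcmc"]])
          else maihda_mcmc_profile(config[["mcmc_profile"]] %||% "test")
  sensitivity <- config$sensitivity %||% "none"
  input <- config$input %||% list(mode = "synthetic")
  outcomes <- config$outcomes %||% input$preset %||% "diarrhea"

  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("maihda")),
    r_version = as.character(getRversion()),
    seed = seed,
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  results <- list()
  for (oc in outcomes) {
    res <- run_one_outcome(oc, input, seed, alpha, v_threshold, prior, mcmc,
                           sensitivity)
    results[[oc]] <- res
    if (!is.null(output_dir)) {
      write_outcome_artifacts(res, oc, output_dir, manifest)
    }
  }
  out <- c(results, list(manifest = manifest))
  if (!is.null(output_dir)) {
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  class(out) <- "maihda_run"
  out
}

run_one_outcome <- function(outcome, input, seed, alpha, v_threshold, prior,
                            mcmc, sensitivity) {
  mode <- input$mode %||% "synthetic"
  if (mode == "synthetic") {
    cfg <- if (!is.null(input$config)) {
      # a ready maihda_sim_config, or a plain list of cohort_config()
      # arguments (e.g. parsed from the YAML run configuration)
      if (inherits(input$config, "maihda_sim_config")) input$config
      else do.call(cohort_config, input$config)
    } else {
      slum_cohort_config(
        outcome = input$preset %||% outcome,
        n = input$n %||% 2199, seed = seed,
        sigma_u = input$sigma_u %||% 0.2)
    }
    cohort <- simulate_cohort(cfg)
    data <- cohort$data
    outcome_col <- cfg$outcome
  } else {
    data <- read_cohort(input$path)
    for (v in intersect(names(analysis_levels()), names(data))) {
      data[[v]] <- factor(data[[v]], levels = analysis_levels()[[v]])
    }
    outcome_col <- outcome
  }
  if (!outcome_col %in% names(data)) stop("outcome column missing: ", outcome_col)

  if (identical(sensitivity, "exclude-dk-education") &&
      "head_education" %in% names(data)) {
    keep <- is.na(data$head_education) |
      data$head_education != "don't know/not applicable"
    data <- droplevels(data[keep, , drop = FALSE])
  }

  candidates <- setdiff(
    intersect(names(analysis_levels()), names(data)), outcome_col)

  drop_report <- complete_case_filter(data, outcome_col, candidates)
  d <- droplevels(drop_report$data)

  screen <- screen_covariates(d, outcome_col, candidates, alpha = alpha)
  if (!any(screen$selected)) {
    stop("no variable passed univariable screening; supply strata variables explicitly")
  }
  vars <- resolve_collinearity(d, screen, threshold = v_threshold)
  strata <- build_strata(d, vars)

  f1 <- stats::reformulate("1", response = outcome_col)
  f2 <- stats::reformulate(vars, response = outcome_col)
  f3 <- stats::reformulate(candidates, response = outcome_col)
  fits <- list(
    `Model 1` = maihda(f1, d, strata, prior, mcmc, seed = seed),
    `Model 2` = maihda(f2, d, strata, prior, mcmc, seed = seed + 1L),
    `Model 3` = maihda(f3, d, strata, prior, mcmc, seed = seed + 2L)
  )
  da <- da_report(fits)
  effects <- lapply(fits, stratum_effects)
  tab1 <- render_table1(fits, da)

  summary_json <- list(
    outcome = outcome_col,
    n_input = drop_report$n_input,
    n_dropped_outcome = drop_report$n_dropped_outcome,
    n_dropped_covariate = drop_report$n_dropped_covariate,
    n_analysis = drop_report$n_kept,
    prevalence_pct = pct(sum(fits[[1]]$y), fits[[1]]$n),
    selected_variables = vars,
    strata_n = strata_summary(strata)$J,
    pct_strata_ge5 = strata_summary(strata)$pct_ge5,
    models = lapply(fits, function(f) list(
      strata_variance = strata_variance(f),
      vpc_pct = vpc(f),
      auc_roc_pct = 100 * auc_roc(f$y, f$p_hat),
      converged = f$converged,
      odds_ratios = odds_ratio_table(f),
      significant_strata = sum(stratum_effects(f)$significant)
    )),
    pcv_pct = setNames(as.list(da$pcv), da$model)
  )

  list(drop_report = drop_report, screen = screen, strata = strata,
       fits = fits, da = da, effects = effects, table1 = tab1,
       summary = summary_json)
}

write_outcome_artifacts <- function(res, outcome, output_dir, manifest) {
  pfx <- function(f) file.path(output_dir, paste0(outcome, "_", f))
  write.csv(as.data.frame(res$screen), pfx("screen.csv"), row.names = FALSE)
  write.csv(res$strata$map, pfx("strata.csv"), row.names = FALSE)
  write.csv(res$table1, pfx("table1.csv"), row.names = FALSE)
  jsonlite::write_json(
    res$summary, pfx("summary.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(n_input = res$drop_report$n_input,
         n_dropped_outcome = res$drop_report$n_dropped_outcome,
         n_dropped_covariate = res$drop_report$n_dropped_covariate,
         n_kept = res$drop_report$n_kept,
         config_hash = manifest$config_hash),
    pfx("drop_report.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    as.data.frame(res$da), pfx("da_report.json"), digits = NA)
  for (m in seq_along(res$effects)) {
    write.csv(caterpillar_data(res$effects[[m]]),
              pfx(sprintf("effects_model%d.csv", m)), row.names = FALSE)
  }
  grDevices::png(pfx("caterpillar.png"), width = 900, height = 1100)
  old <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  for (m in seq_along(res$effects)) {
    plot(res$effects[[m]], main = sprintf("%s - Model %d", outcome, m))
  }
  graphics::par(old)
  grDevices::dev.off()
  invisible(NULL)
}

#' Render the combined results table of a MAIHDA model sequence
#'
#' One column per model with `OR (lower, upper)` cells (reference levels as
#' `1.00`, significance asterisks when the 95% interval excludes 1) and the
#' bottom block of strata variance, strata N, individual N, AUC-ROC, VPC
#' and PCV, mirroring the standard reporting layout for these analyses.
#'
#' @param fits named list of [maihda] fits, ordered Model 1..k, all on the
#'   same data; or a named list of per-outcome `list(fits =, da =)` blocks
#'   for a multi-outcome table.
#' @param da optional [da_report()] (computed when omitted).
#' @param digits decimals for ORs.
#' @return character data frame with a `term` column and one column per
#'   model (per outcome).
#' @export
render_table1 <- function(fits, da = NULL, digits = 2) {
  if (!inherits(fits[[1]], "maihda_fit")) {
    blocks <- lapply(names(fits), function(oc) {
      b <- render_table1(fits[[oc]]$fits, fits[[oc]]$da, digits)
      names(b)[-1] <- paste(oc, names(b)[-1])
      b
    })
    out <- Reduce(function(a, b) merge(a, b, by = "term", all = TRUE,
                                       sort = FALSE), blocks)
    out[is.na(out)] <- ""
    return(out)
  }
  stopifnot(all(vapply(fits, inherits, TRUE, "maihda_fit")))
  if (is.null(da)) da <- da_report(fits)
  if (is.null(names(fits))) names(fits) <- paste("Model", seq_along(fits))

  fmt <- function(or, lo, hi, sig) {
    s <- sprintf(paste0("%.", digits, "f(%.", digits, "f, %.", digits, "f)"),
                 or, lo, hi)
    ifelse(!is.na(sig) & sig, paste0(s, "*"), s)
  }
  # full term layout from the widest model: variable header rows with the
  # reference level, then one row per non-reference level
  ref_fit <- fits[[which.max(vapply(fits, function(f) length(f$coef_names), 0))]]
  terms_all <- c("(Intercept)")
  ref_rows <- character()
  for (v in names(ref_fit$xlevels)) {
    lv <- ref_fit$xlevels[[v]]
    ref_rows <- c(ref_rows, paste0(v, ": ", lv[1], " (ref)"))
    terms_all <- c(terms_all, paste0(v, ": ", lv[1], " (ref)"),
                   paste0(v, lv[-1]))
  }
  tab <- data.frame(term = terms_all)
  for (m in names(fits)) {
    f <- fits[[m]]
    ot <- odds_ratio_table(f)
    cells <- setNames(fmt(ot$or, ot$lower, ot$upper, ot$significant), ot$term)
    col <- character(length(terms_all))
    for (i in seq_along(terms_all)) {
      tm <- terms_all[i]
      if (tm %in% names(cells)) {
        col[i] <- cells[[tm]]
      } else if (tm %in% ref_rows) {
        v <- sub(":.*$", "", tm)
        col[i] <- if (v %in% names(f$xlevels)) "1.00" else ""
      } else {
        col[i] <- ""
      }
    }
    tab[[m]] <- col
  }
  bottom <- data.frame(
    term = c("Strata variance", "Strata N", "Individual N", "AUC-ROC",
             "VPC", "PCV"))
  for (k in seq_along(fits)) {
    bottom[[names(fits)[k]]] <- c(
      sprintf("%.2f", da$strata_variance[k]),
      format(da$strata_n[k]),
      format(da$individual_n[k], big.mark = ","),
      sprintf("%.2f%%", 100 * da$auc_roc[k]),
      sprintf("%.2f%%", da$vpc[k]),
      if (k == 1) "" else sprintf("%.2f%%", da$pcv[k]))
  }
  rbind(tab, bottom)
}

config_hash <- function(config) {
  config$timestamp <- NULL
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' @export
print.maihda_run <- function(x, ...) {
  ocs <- setdiff(names(x), "manifest")
  cat(sprintf("MAIHDA pipeline run (seed %d, config %s)\n",
              x$manifest$seed, substr(x$manifest$config_hash, 1, 8)))
  for (oc in ocs) {
    s <- x[[oc]]$summary
    cat(sprintf(
      "  %s: n = %s, %d strata; VPC %% (M1/M2/M3) = %.2f/%.2f/%.2f\n",
      oc, format(s$n_analysis, big.mark = ","), s$strata_n,
      s$models[[1]]$vpc_pct, s$models[[2]]$vpc_pct, s$models[[3]]$vpc_pct))
  }
  invisible(x)
}
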
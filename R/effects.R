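#' Stratum-level intersectional estimates
#'
#' Posterior summaries of the stratum random effects `u_j`: the estimate
#' (posterior mean by default), an equal-tailed 95% credible interval,
#' ascending rank (ties broken by stratum ID), a significance flag (the
#' interval excludes 0) and a direction label. A positive estimate means
#' children in that stratum have a higher risk than expected from adding up
#' the effects of the variables that define it; a negative estimate, lower.
#'
#' @param fit a [maihda] fit containing `u_j` draws for every stratum.
#' @param stat `"mean"` (default) or `"median"` posterior summary.
#' @param prob credible-interval probability.
#' @return data frame of class `maihda_stratum_effects` with columns
#'   `stratum`, `label`, `n`, `estimate`, `lower`, `upper`, `rank`,
#'   `significant`, `direction`.
#' @export
stratum_effects <- function(fit, stat = c("mean", "median"), prob = 0.95) {
  stopifnot(inherits(fit, "maihda_fit"))
  stat <- match.arg(stat)
  u <- fit$draws$u
  if (is.null(u) || ncol(u) != fit$J) stop("fit is missing stratum-effect draws")
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  est <- if (stat == "mean") colMeans(u) else apply(u, 2, median)
  lo <- apply(u, 2, quantile, probs = qs[1])
  hi <- apply(u, 2, quantile, probs = qs[2])
  rk <- rank(est, ties.method = "first")  # ties broken by stratum ID order
  out <- data.frame(
    stratum = fit$strata_map$stratum,
    label = fit$strata_map$label,
    n = fit$strata_map$n,
    estimate = unname(est),
    lower = unname(lo),
    upper = unname(hi),
    rank = as.integer(rk),
    significant = unname(lo > 0 | hi < 0),
    direction = ifelse(est >= 0, "higher", "lower")
  )
  class(out) <- c("maihda_stratum_effects", "data.frame")
  out
}

#' Caterpillar-plot records
#'
#' Stratum effects ordered by ascending rank, with a colour key separating
#' significant from non-significant intervals — the data behind the ranked
#' interval ("caterpillar") plot.
#'
#' @param effects a [stratum_effects()] table.
#' @return the table sorted by `rank` with an added `colour` column.
#' @export
caterpillar_data <- function(effects) {
  stopifnot(inherits(effects, "maihda_stratum_effects"))
  out <- effects[order(effects$rank), , drop = FALSE]
  out$colour <- ifelse(out$significant, "firebrick", "grey40")
  rownames(out) <- NULL
  out
}

#' @export
plot.maihda_stratum_effects <- function(x, main = "Intersectional estimates",
                                        ylab = "stratum effect (log-odds)",
                                        ...) {
  d <- caterpillar_data(x)
  plot(d$rank, d$estimate, ylim = range(d$lower, d$upper), pch = 16,
       cex = 0.5, col = d$colour, xlab = "stratum rank", ylab = ylab,
       main = main, ...)
  graphics::segments(d$rank, d$lower, d$rank, d$upper, col = d$colour)
  graphics::abline(h = 0, lty = 2)
  invisible(d)
}

#' @export
print.maihda_stratum_effects <- function(x, ...) {
  cat(sprintf("Stratum-level intersectional estimates (%d strata; %d significant)\n",
              nrow(x), sum(x$significant)))
  NextMethod()
}
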
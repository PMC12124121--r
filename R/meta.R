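#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools per-cohort causal estimates for one exposure-outcome pair on
#' the log-odds scale. Fixed weights are `w_i = 1 / se_i^2`; Cochran's
#' `Q` is computed about the fixed pooled value; the between-cohort
#' variance is the moment estimator
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))`;
#' random-effects weights `1 / (se_i^2 + tau2)` give the pooled beta,
#' its SE, normal 95% CI and two-sided p. `I2 = max(0, (Q - df) / Q)`
#' summarizes the heterogeneity fraction.
#'
#' @param estimates per-cohort inputs: either a data frame with columns
#'   `beta` and `se` (and optionally `cohort`), or a list of
#'   [mr_estimate()]s (names become cohort labels).
#' @return A list of class `meta_result`: `beta`, `se`, `ci_low`,
#'   `ci_high`, `pval`, `tau2`, `Q`, `df`, `q_pval`, `I2`, `k`,
#'   `fixed` (the fixed-effect pooled beta and se) and `cohorts`
#'   (the echoed inputs with their random-effects weights).
#' @export
pool_random_effects <- function(estimates) {
  d <- meta_inputs(estimates)
  k <- nrow(d)
  if (k < 2L) stop("meta-analysis needs at least 2 cohort estimates", call. = FALSE)
  w <- 1 / d$se^2
  beta_f <- sum(w * d$beta) / sum(w)
  se_f <- sqrt(1 / sum(w))
  Q <- sum(w * (d$beta - beta_f)^2)
  df <- k - 1L
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (d$se^2 + tau2)
  beta <- sum(wr * d$beta) / sum(wr)
  se <- sqrt(1 / sum(wr))
  d$weight_pct <- 100 * wr / sum(wr)
  structure(list(
    beta = beta, se = se,
    ci_low = beta - stats::qnorm(0.975) * se,
    ci_high = beta + stats::qnorm(0.975) * se,
    pval = two_sided_p(beta / se),
    tau2 = tau2, Q = Q, df = df,
    q_pval = stats::pchisq(Q, df, lower.tail = FALSE),
    I2 = max(0, (Q - df) / Q), k = k,
    fixed = c(beta = beta_f, se = se_f),
    cohorts = d
  ), class = "meta_result")
}

meta_inputs <- function(estimates) {
  if (is.data.frame(estimates)) {
    stopifnot(all(c("beta", "se") %in% names(estimates)))
    d <- data.frame(
      cohort = if ("cohort" %in% names(estimates)) as.character(estimates$cohort)
               else sprintf("cohort_%d", seq_len(nrow(estimates))),
      beta = as.numeric(estimates$beta), se = as.numeric(estimates$se),
      stringsAsFactors = FALSE)
  } else if (is.list(estimates)) {
    stopifnot(all(vapply(estimates, inherits, TRUE, "mr_estimate")))
    d <- data.frame(
      cohort = names(estimates) %||% sprintf("cohort_%d", seq_along(estimates)),
      beta = vapply(estimates, `[[`, 0, "beta"),
      se = vapply(estimates, `[[`, 0, "se"),
      stringsAsFactors = FALSE)
  } else stop("unsupported input for meta-analysis", call. = FALSE)
  if (any(!is.finite(d$beta)) || any(!is.finite(d$se)) || any(d$se <= 0))
    stop("meta-analysis inputs must have finite betas and positive ses",
         call. = FALSE)
  rownames(d) <- NULL
  d
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Random-effects meta-analysis of %d cohorts\npooled OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\ntau2 = %.5f, Q = %.3f (df %d, p = %.3g), I2 = %.1f%%\n",
    x$k, exp(x$beta), exp(x$ci_low), exp(x$ci_high), x$pval,
    x$tau2, x$Q, x$df, x$q_pval, 100 * x$I2))
  invisible(x)
}

#' Forest-plot table for a pooled result
#'
#' Lays out the per-cohort odds ratios, confidence intervals and
#' random-effects weights plus a pooled summary row, i.e. the content of
#' a forest plot as a plain table.
#'
#' @param meta a [pool_random_effects()] result.
#' @return Data frame with columns `cohort`, `or`, `ci_low`, `ci_high`,
#'   `weight_pct`; the last row is the pooled estimate.
#' @export
forest_table <- function(meta) {
  stopifnot(inherits(meta, "meta_result"))
  z <- stats::qnorm(0.975)
  rows <- data.frame(
    cohort = meta$cohorts$cohort,
    or = exp(meta$cohorts$beta),
    ci_low = exp(meta$cohorts$beta - z * meta$cohorts$se),
    ci_high = exp(meta$cohorts$beta + z * meta$cohorts$se),
    weight_pct = meta$cohorts$weight_pct,
    stringsAsFactors = FALSE)
  rbind(rows, data.frame(cohort = "pooled", or = exp(meta$beta),
                         ci_low = exp(meta$ci_low), ci_high = exp(meta$ci_high),
                         weight_pct = 100))
}
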
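#' Two-step MR mediation decomposition
#'
#' Partitions a total causal effect `c` of an exposure (e.g. total or
#' LDL cholesterol) on an outcome into the component routed through a
#' mediator (a lipid species) and the remainder: the indirect effect is
#' the product `a * b` of the exposure-to-mediator effect `a` and the
#' mediator-to-outcome effect `b`, the direct effect is `c - a * b`, and
#' the proportion mediated is `a * b / c`.
#'
#' Uncertainty is first-order delta method with `a`, `b`, `c` treated as
#' mutually independent (they come from separate two-sample MR fits, so
#' no covariance is estimable):
#' `se(ab) = sqrt(a^2 se_b^2 + b^2 se_a^2)` and
#' `se(prop) = |prop| * sqrt(se_a^2/a^2 + se_b^2/b^2 + se_c^2/c^2)`.
#' The mediation test is the Wald z of the proportion against zero with
#' a symmetric normal 95% CI — the construction implied by symmetric
#' reported intervals around a mediated proportion.
#'
#' @param a,se_a exposure-to-mediator effect and SE.
#' @param b,se_b mediator-to-outcome effect and SE (log-odds scale for a
#'   binary outcome).
#' @param c_total,se_c total exposure-to-outcome effect and SE.
#' @return A list of class `mediation_result`: `a`, `se_a`, `b`, `se_b`,
#'   `c`, `se_c`, `indirect`, `se_indirect`, `direct`, `se_direct`,
#'   `proportion`, `se_proportion`, `ci_low`, `ci_high`, `z`, `pval`.
#'   The identity `indirect + direct == c` holds exactly.
#' @export
two_step_mediation <- function(a, se_a, b, se_b, c_total, se_c) {
  for (nm in c("a", "b", "c_total")) check_scalar(get(nm), nm)
  for (nm in c("se_a", "se_b", "se_c"))
    check_scalar(get(nm), nm, lower = 0, strict_lower = TRUE)
  if (abs(c_total) < 1e-12)
    stop("total effect ~ 0, proportion mediated undefined", call. = FALSE)
  indirect <- a * b
  se_indirect <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  direct <- c_total - indirect
  se_direct <- sqrt(se_c^2 + se_indirect^2)
  proportion <- indirect / c_total
  rel <- if (indirect == 0) {
    # a or b is exactly zero: the proportion is 0 and only the non-zero
    # legs contribute first-order variance
    terms <- c(if (a != 0) se_a^2 / a^2, if (b != 0) se_b^2 / b^2,
               se_c^2 / c_total^2)
    sqrt(sum(terms))
  } else {
    sqrt(se_a^2 / a^2 + se_b^2 / b^2 + se_c^2 / c_total^2)
  }
  se_proportion <- if (indirect == 0) {
    # delta method collapses at ab = 0; propagate the product SE instead
    se_indirect / abs(c_total)
  } else {
    abs(proportion) * rel
  }
  z <- proportion / se_proportion
  structure(list(
    a = a, se_a = se_a, b = b, se_b = se_b, c = c_total, se_c = se_c,
    indirect = indirect, se_indirect = se_indirect,
    direct = direct, se_direct = se_direct,
    proportion = proportion, se_proportion = se_proportion,
    ci_low = proportion - stats::qnorm(0.975) * se_proportion,
    ci_high = proportion + stats::qnorm(0.975) * se_proportion,
    z = z, pval = two_sided_p(z)
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "Two-step MR mediation\n  a = %.4f (se %.4f), b = %.4f (se %.4f), total c = %.4f (se %.4f)\n  indirect = %.4f, direct = %.4f\n  proportion mediated = %.1f%% (95%% CI %.1f%% to %.1f%%), p = %.3g\n",
    x$a, x$se_a, x$b, x$se_b, x$c, x$se_c, x$indirect, x$direct,
    100 * x$proportion, 100 * x$ci_low, 100 * x$ci_high, x$pval))
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(a = x$a, se_a = x$se_a, b = x$b, se_b = x$se_b,
             c = x$c, se_c = x$se_c, indirect = x$indirect,
             direct = x$direct, proportion_pct = 100 * x$proportion,
             ci_low_pct = 100 * x$ci_low, ci_high_pct = 100 * x$ci_high,
             pval = x$pval, stringsAsFactors = FALSE)
}

#' Recover a Wald p-value from a printed OR and 95% CI
#'
#' Inverts the standard reporting convention `OR (95% CI)` back to the
#' two-sided normal p-value of the underlying log-odds estimate:
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.959964)` and
#' `p = 2 * pnorm(-|log(or) / se|)`. Used to check published
#' OR/CI/p rows for internal consistency.
#'
#' @param or_value odds ratio point estimate.
#' @param ci_low,ci_high bounds of the 95% confidence interval; both
#'   must be positive and bracket `or_value` (a printed lower bound of
#'   0.000 cannot be inverted).
#' @return The two-sided p-value.
#' @export
wald_p_from_or_ci <- function(or_value, ci_low, ci_high) {
  if (!is.finite(ci_low) || ci_low <= 0)
    stop("ci_low must be positive; a printed 0.000 bound is not invertible",
         call. = FALSE)
  if (!(ci_low < or_value && or_value < ci_high))
    stop("need 0 < ci_low < or_value < ci_high", call. = FALSE)
  se <- (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975))
  two_sided_p(log(or_value) / se)
}
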
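#' MR causal-effect estimates
#'
#' Container for one estimator's result: the causal effect `beta` (log
#' odds per exposure unit for binary outcomes), its `se`, symmetric 95%
#' normal confidence interval, two-sided normal p-value, SNP count and
#' method-specific extras (e.g. the Egger intercept).
#'
#' @param method estimator label.
#' @param beta,se point estimate and standard error.
#' @param n_snps number of instruments used.
#' @param extra named list of method-specific quantities.
#' @return A list of class `mr_estimate`.
#' @keywords internal
mr_estimate <- function(method, beta, se, n_snps, extra = list()) {
  ci_half <- stats::qnorm(0.975) * se
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = beta - ci_half, ci_high = beta + ci_half,
    pval = two_sided_p(beta / se), n_snps = as.integer(n_snps),
    extra = extra
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g, %d SNP(s)\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snps))
  if (!is.null(x$extra$intercept))
    cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g\n",
                x$extra$intercept, x$extra$intercept_se, x$extra$intercept_p))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             or = exp(x$beta), or_ci_low = exp(x$ci_low),
             or_ci_high = exp(x$ci_high), stringsAsFactors = FALSE)
}

#' Single-SNP Wald ratio
#'
#' The per-SNP causal estimate `beta_out / beta_exp` with the standard
#' first-order SE `|se_out / beta_exp|` (exposure uncertainty ignored,
#' as in conventional IVW weighting); `second_order = TRUE` adds the
#' exposure-noise term
#' `sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)`.
#'
#' @param beta_exp,se_exp,beta_out,se_out scalars for one SNP.
#' @param second_order use the second-order SE (default `FALSE`).
#' @return An [mr_estimate()] with method `"wald"`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       second_order = FALSE) {
  if (beta_exp == 0)
    stop("Wald ratio undefined for beta_exp = 0", call. = FALSE)
  beta <- beta_out / beta_exp
  se <- if (second_order) {
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  } else {
    abs(se_out / beta_exp)
  }
  mr_estimate("wald", beta, se, 1L)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights `1 / se_out^2`:
#' `beta = sum(w * bx * by) / sum(w * bx^2)`. The fixed-effect SE is
#' `1 / sqrt(sum(w * bx^2))`; the multiplicative-random-effects model
#' (`model = "mre"`) inflates it by `sqrt(max(1, Q / (k - 1)))` where
#' `Q` is Cochran's statistic about the fitted slope, so the MRE SE is
#' never smaller than the fixed one.
#'
#' @param hset a [harmonize()]d set with at least two SNPs.
#' @param model `"fe"` (fixed) or `"mre"` (multiplicative random effects).
#' @return An [mr_estimate()]; `extra` carries `Q` and `q_pval`.
#' @export
mr_ivw <- function(hset, model = c("fe", "mre")) {
  model <- match.arg(model)
  stopifnot(inherits(hset, "harmonized_set"))
  k <- nrow(hset)
  if (k < 2L)
    stop("IVW needs at least 2 SNPs; use wald_ratio() for a single instrument",
         call. = FALSE)
  w <- 1 / hset$se_out^2
  bx <- hset$beta_exp
  by <- hset$beta_out
  denom <- sum(w * bx^2)
  beta <- sum(w * bx * by) / denom
  se_fe <- sqrt(1 / denom)
  Q <- sum(w * (by - beta * bx)^2)
  se <- if (model == "mre") se_fe * sqrt(max(1, Q / (k - 1))) else se_fe
  mr_estimate(paste0("ivw_", model), beta, se, k,
              extra = list(Q = Q, q_df = k - 1L,
                           q_pval = stats::pchisq(Q, k - 1L, lower.tail = FALSE)))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with a
#' free intercept (weights `1 / se_out^2`), after orienting all exposure
#' betas to be non-negative (outcome betas flip sign in tandem). The
#' slope is the causal estimate; a non-zero intercept indicates
#' directional horizontal pleiotropy. Both SEs carry the multiplicative
#' random-effects inflation `sqrt(max(1, Q_egger / (k - 2)))`.
#'
#' @param hset a [harmonize()]d set with at least three SNPs.
#' @return An [mr_estimate()] with method `"egger"`; `extra` carries
#'   `intercept`, `intercept_se`, `intercept_p`, `Q`, `q_df`, `q_pval`.
#' @export
mr_egger <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  k <- nrow(hset)
  if (k < 3L) stop("MR-Egger needs at least 3 SNPs", call. = FALSE)
  flip <- sign(hset$beta_exp)
  flip[flip == 0] <- 1
  bx <- hset$beta_exp * flip
  by <- hset$beta_out * flip
  w <- 1 / hset$se_out^2

  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
  det <- sw * sxx - swx^2
  if (det <= 0) stop("MR-Egger design is degenerate (no spread in beta_exp)",
                     call. = FALSE)
  slope <- (sw * sxy - swx * swy) / det
  intercept <- (swy - slope * swx) / sw
  resid <- by - intercept - slope * bx
  Q <- sum(w * resid^2)
  inflate <- sqrt(max(1, Q / (k - 2)))
  se_slope <- sqrt(sw / det) * inflate
  se_int <- sqrt(sxx / det) * inflate
  mr_estimate("egger", slope, se_slope, k,
              extra = list(intercept = intercept, intercept_se = se_int,
                           intercept_p = two_sided_p(intercept / se_int),
                           Q = Q, q_df = k - 2L,
                           q_pval = stats::pchisq(Q, k - 2L, lower.tail = FALSE)))
}

# Wald ratios and their first-order inverse-variance weights.
ratio_weights <- function(hset) {
  bx <- hset$beta_exp
  list(ratio = hset$beta_out / bx, w = (bx / hset$se_out)^2)
}

# Weighted median of `x` with weights `w`: sort, accumulate weight, take
# the value whose mass straddles 0.5 (midpoint of neighbours if 0.5 falls
# exactly on a boundary between two SNPs' mass).
weighted_median_point <- function(x, w) {
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  j <- which(cw >= 0.5)[1]
  if (abs(cw[j] - 0.5) < 1e-12 && j < length(x)) (x[j] + x[j + 1]) / 2 else x[j]
}

# Parametric bootstrap SE over re-drawn (beta_exp, beta_out).
bootstrap_se <- function(hset, point_fun, n_boot, seed) {
  with_seed(seed, {
    k <- nrow(hset)
    est <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, hset$beta_exp, hset$se_exp)
      by <- stats::rnorm(k, hset$beta_out, hset$se_out)
      point_fun(by / bx, (bx / hset$se_out)^2)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted-median estimator
#'
#' Orders per-SNP Wald ratios and takes the ratio at cumulative
#' normalized inverse-variance weight 0.5; consistent when at least half
#' the weight comes from valid instruments. The SE is a parametric
#' bootstrap over redrawn exposure and outcome betas.
#'
#' @param hset a [harmonize()]d set with at least three SNPs.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An [mr_estimate()] with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(hset, "harmonized_set"))
  if (nrow(hset) < 3L) stop("weighted median needs at least 3 SNPs", call. = FALSE)
  rw <- ratio_weights(hset)
  beta <- weighted_median_point(rw$ratio, rw$w)
  se <- bootstrap_se(hset, weighted_median_point, n_boot, seed)
  mr_estimate("weighted_median", beta, se, nrow(hset))
}

# Mode of a weighted kernel density over the ratios; Silverman-flavoured
# bandwidth `phi * 0.9 * min(sd, mad) * k^(-1/5)` as in the standard
# mode-based estimator. Degenerate spread returns the common value.
weighted_mode_point <- function(ratio, w, phi = 1) {
  s <- min(stats::sd(ratio), stats::mad(ratio))
  if (!is.finite(s) || s <= 0) return(stats::median(ratio))
  h <- phi * 0.9 * s * length(ratio)^(-1 / 5)
  d <- stats::density(ratio, weights = w / sum(w), bw = h, n = 1024)
  d$x[which.max(d$y)]
}

#' Weighted-mode estimator
#'
#' Kernel-density (normal kernel) mode of the per-SNP Wald ratios with
#' inverse-variance weights; consistent when the largest group of
#' instruments sharing one causal effect is valid. `phi` scales the
#' default bandwidth. The SE is a parametric bootstrap as in
#' [mr_weighted_median()].
#'
#' @param hset a [harmonize()]d set with at least three SNPs.
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An [mr_estimate()] with method `"weighted_mode"`; `extra`
#'   carries the bandwidth multiplier.
#' @export
mr_weighted_mode <- function(hset, phi = 1, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(hset, "harmonized_set"))
  if (nrow(hset) < 3L) stop("weighted mode needs at least 3 SNPs", call. = FALSE)
  check_scalar(phi, "phi", lower = 0, strict_lower = TRUE)
  rw <- ratio_weights(hset)
  beta <- weighted_mode_point(rw$ratio, rw$w, phi)
  se <- bootstrap_se(hset, function(r, w) weighted_mode_point(r, w, phi),
                     n_boot, seed)
  mr_estimate("weighted_mode", beta, se, nrow(hset), extra = list(phi = phi))
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_i * (ratio_i - reference_beta)^2)` over per-SNP Wald
#' ratios with first-order inverse-variance weights
#' `w_i = (beta_exp_i / se_out_i)^2`, compared to a chi-square with
#' `df` degrees of freedom (`k - 1` about an IVW fit, `k - 2` about an
#' Egger fit). p below 0.05 flags heterogeneity.
#'
#' @param hset a [harmonize()]d set with at least two SNPs.
#' @param reference_beta the causal estimate the ratios are compared to.
#' @param df degrees of freedom; defaults to `nrow(hset) - 1`.
#' @return A list of class `q_test` with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(hset, reference_beta, df = NULL) {
  stopifnot(inherits(hset, "harmonized_set"))
  k <- nrow(hset)
  if (k < 2L) stop("Q test needs at least 2 SNPs", call. = FALSE)
  rw <- ratio_weights(hset)
  Q <- sum(rw$w * (rw$ratio - reference_beta)^2)
  df <- df %||% (k - 1L)
  if (df < 1L) stop("Q test needs df >= 1", call. = FALSE)
  structure(list(Q = Q, df = as.integer(df),
                 pval = stats::pchisq(Q, df, lower.tail = FALSE)),
            class = "q_test")
}

#' @export
print.q_test <- function(x, ...) {
  cat(sprintf("Cochran Q = %.3f on %d df, p = %.3g\n", x$Q, x$df, x$pval))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the IVW estimator once per omitted SNP, using the IVW variant
#' (fixed vs multiplicative random effects) selected on the full set by
#' its heterogeneity test, so every row is comparable to the full fit.
#'
#' @param hset a [harmonize()]d set with at least three SNPs.
#' @return Data frame with one row per omitted SNP: `snp`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`; attribute `full` holds the full-set
#'   estimate.
#' @export
leave_one_out <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  if (nrow(hset) < 3L) stop("leave-one-out needs at least 3 SNPs", call. = FALSE)
  full_fe <- mr_ivw(hset, "fe")
  model <- if (full_fe$extra$q_pval < 0.05) "mre" else "fe"
  full <- mr_ivw(hset, model)
  rows <- lapply(seq_len(nrow(hset)), function(i) {
    est <- mr_ivw(hset[-i, , drop = FALSE], model)
    data.frame(snp = hset$snp[i], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}

#' Choose the primary estimate
#'
#' The reporting rule of the workflow: MR-Egger is preferred when its
#' intercept signals directional pleiotropy (intercept p below 0.05
#' *and* absolute intercept of at least 0.01, the compound reading of a
#' "no pleiotropy" declaration as intercept < 0.01 with p > 0.05);
#' otherwise the multiplicative-random-effects IVW under heterogeneity
#' (Q p below 0.05), otherwise the fixed-effect IVW.
#'
#' @param ivw_fe,ivw_mre,egger the candidate [mr_estimate()]s; `egger`
#'   may be `NULL` when fewer than three SNPs were available.
#' @param q a [cochran_q()] result for the IVW fit.
#' @param intercept_p,intercept optional overrides; default to the
#'   values stored in `egger$extra`.
#' @return The chosen [mr_estimate()], with `extra$selection` recording
#'   the rule outcome.
#' @export
select_primary <- function(ivw_fe, ivw_mre, egger = NULL, q,
                           intercept_p = NULL, intercept = NULL) {
  intercept_p <- intercept_p %||% egger$extra$intercept_p
  intercept <- intercept %||% egger$extra$intercept
  pleiotropic <- !is.null(egger) && !is.null(intercept_p) &&
    intercept_p < 0.05 && abs(intercept) >= 0.01
  chosen <- if (pleiotropic) {
    egger
  } else if (q$pval < 0.05) {
    ivw_mre
  } else {
    ivw_fe
  }
  chosen$extra$selection <- if (pleiotropic) "pleiotropy" else if (q$pval < 0.05)
    "heterogeneity" else "homogeneous"
  chosen
}

#' Run the full estimator suite on a harmonized set
#'
#' Convenience wrapper fitting IVW (both variants), MR-Egger, weighted
#' median and weighted mode (when enough SNPs), the heterogeneity and
#' pleiotropy diagnostics, and applying [select_primary()]. With one SNP
#' the Wald ratio is the primary estimate; with two, the IVW pair.
#'
#' @param hset a [harmonize()]d set.
#' @param n_boot bootstrap replicates for median/mode (default 1000).
#' @param phi weighted-mode bandwidth multiplier.
#' @param seed RNG seed for the bootstraps.
#' @return A list of class `mr_suite`: `primary`, `estimates` (named
#'   list of [mr_estimate()]s), `q` (IVW-referenced [cochran_q()]),
#'   `n_snps`, `status` (`"ok"`, `"single_snp"` or
#'   `"insufficient_instruments"`).
#' @export
mr_suite <- function(hset, n_boot = 1000, phi = 1, seed = NULL) {
  stopifnot(inherits(hset, "harmonized_set"))
  k <- nrow(hset)
  if (k == 0L)
    return(structure(list(primary = NULL, estimates = list(), q = NULL,
                          n_snps = 0L, status = "insufficient_instruments"),
                     class = "mr_suite"))
  if (k == 1L) {
    est <- wald_ratio(hset$beta_exp, hset$se_exp, hset$beta_out, hset$se_out)
    return(structure(list(primary = est, estimates = list(wald = est),
                          q = NULL, n_snps = 1L, status = "single_snp"),
                     class = "mr_suite"))
  }
  fe <- mr_ivw(hset, "fe")
  mre <- mr_ivw(hset, "mre")
  q <- cochran_q(hset, fe$beta)
  ests <- list(ivw_fe = fe, ivw_mre = mre)
  egger <- NULL
  if (k >= 3L) {
    egger <- mr_egger(hset)
    ests$egger <- egger
    ests$weighted_median <- mr_weighted_median(hset, n_boot = n_boot, seed = seed)
    ests$weighted_mode <- mr_weighted_mode(hset, phi = phi, n_boot = n_boot,
                                           seed = if (is.null(seed)) NULL else seed + 1L)
  }
  primary <- select_primary(fe, mre, egger, q)
  structure(list(primary = primary, estimates = ests, q = q,
                 n_snps = k, status = "ok"),
            class = "mr_suite")
}

#' @export
print.mr_suite <- function(x, ...) {
  cat(sprintf("MR suite over %d SNP(s), status: %s\n", x$n_snps, x$status))
  if (!is.null(x$primary)) {
    cat("primary -> ")
    print(x$primary)
  }
  invisible(x)
}
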
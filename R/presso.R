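#' MR-PRESSO global test and outlier detection
#'
#' Simulation-based residual test for horizontal-pleiotropy outliers.
#' The observed statistic is the leave-one-out weighted residual sum of
#' squares: each SNP's outcome beta is compared with the IVW prediction
#' fitted on all other SNPs, weighted by `1 / se_out^2`. A null
#' distribution is built by redrawing each outcome beta from
#' `Normal(loo_prediction_i, se_out_i)` and recomputing the
#' leave-one-out residuals on every simulated dataset. The global
#' p-value is `(1 + #{simulated RSS >= observed}) / (n_sim + 1)`;
#' per-SNP outlier p-values compare each observed weighted squared
#' residual with its simulated counterparts, with Bonferroni flagging
#' at `outlier_alpha / k`.
#'
#' @param hset a [harmonize()]d set with at least four SNPs.
#' @param n_sim number of null simulations (default 1000; fewer than
#'   100 triggers a warning since the p-value resolution is
#'   `1 / (n_sim + 1)`).
#' @param outlier_alpha family-wise outlier significance level before
#'   Bonferroni division by the SNP count (default 0.05).
#' @param seed RNG seed making the simulation reproducible.
#' @return A list of class `presso_result`: `rss_obs`, `global_p`,
#'   `outlier_p` (named per-SNP), `outliers` (SNP ids flagged),
#'   `n_sim`, `seed`.
#' @export
mr_presso <- function(hset, n_sim = 1000, outlier_alpha = 0.05, seed = NULL) {
  stopifnot(inherits(hset, "harmonized_set"))
  k <- nrow(hset)
  if (k < 4L) stop("MR-PRESSO needs at least 4 SNPs", call. = FALSE)
  check_scalar(outlier_alpha, "outlier_alpha", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (n_sim < 100) warning("n_sim < 100 gives a coarse p-value resolution",
                           call. = FALSE)
  bx <- hset$beta_exp
  by <- hset$beta_out
  w <- 1 / hset$se_out^2
  wb <- w * bx
  s1 <- sum(wb * by)
  s2 <- sum(wb * bx)
  loo_beta <- (s1 - wb * by) / (s2 - wb * bx)
  pred <- loo_beta * bx
  obs_sq <- w * (by - pred)^2
  rss_obs <- sum(obs_sq)

  with_seed(seed, {
    BY <- matrix(stats::rnorm(n_sim * k, mean = rep(pred, each = n_sim),
                              sd = rep(hset$se_out, each = n_sim)),
                 nrow = n_sim, ncol = k)
    S1 <- as.vector(BY %*% wb)
    # per-simulation leave-one-out slopes, vectorized over SNPs
    slope <- (S1 - sweep(BY, 2, wb, `*`)) /
      matrix(s2 - wb * bx, n_sim, k, byrow = TRUE)
    resid_sq <- sweep((BY - sweep(slope, 2, bx, `*`))^2, 2, w, `*`)
    rss_sim <- rowSums(resid_sq)
    global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
    outlier_p <- (1 + colSums(resid_sq >= matrix(obs_sq, n_sim, k, byrow = TRUE))) /
      (n_sim + 1)
    names(outlier_p) <- hset$snp
    outliers <- hset$snp[outlier_p < outlier_alpha / k]
    structure(list(rss_obs = rss_obs, global_p = global_p,
                   outlier_p = outlier_p, outliers = outliers,
                   n_sim = as.integer(n_sim), seed = seed),
              class = "presso_result")
  })
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: observed RSS = %.3f, global p = %.4g (%d simulations)\n",
              x$rss_obs, x$global_p, x$n_sim))
  if (length(x$outliers)) {
    cat("outliers:", paste(x$outliers, collapse = ", "), "\n")
  } else {
    cat("no outliers flagged\n")
  }
  invisible(x)
}
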
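#' Replicated simulation studies
#'
#' Parameter-recovery and calibration experiments over the synthetic
#' GWAS generator. Each function runs `n_reps` independent replicates
#' (replicate `r` uses generator seed `seed + r`) and returns one row
#' per replicate, so calibration rates and Monte-Carlo summaries can be
#' computed by the caller.
#'
#' @name experiments
NULL

# Re-seed a sim_config for one replicate.
rep_config <- function(config, seed, r) {
  config$seed <- seed + r
  config
}

#' Calibration/recovery study for the core estimator suite
#'
#' For each replicate: simulate a triplet, select instruments at the
#' exposure significance threshold (as the screening workflow does —
#' this also guarantees instruments have well-determined effect signs),
#' harmonize against the outcome, fit fixed- and
#' multiplicative-random-effects IVW, MR-Egger and Cochran's Q, and
#' apply the primary-selection rule.
#'
#' @param n_reps number of replicates.
#' @param config a [sim_config()] (its `seed` field is overridden per
#'   replicate).
#' @param p_threshold exposure instrument threshold (default 5e-6);
#'   `NULL` uses every simulated SNP.
#' @param seed base seed.
#' @return Data frame with one row per replicate: `ivw_beta`, `ivw_se`,
#'   `ivw_covered` (fixed-effect 95% CI contains `theta_total`),
#'   `primary_beta`, `primary_p`, `primary_covered`, `q_pval`,
#'   `egger_beta`, `egger_intercept`, `egger_intercept_p`, `n_snps`.
#' @export
mr_calibration_study <- function(n_reps, config = sim_config(),
                                 p_threshold = 5e-6, seed = 1L) {
  theta <- config$theta_total
  rows <- lapply(seq_len(n_reps), function(r) {
    sim <- simulate_triplet(rep_config(config, seed, r))
    sig <- if (is.null(p_threshold)) sim$exposure else
      threshold_instruments(sim$exposure, p_threshold)
    h <- harmonize(sig, sim$outcome)
    fe <- mr_ivw(h, "fe")
    mre <- mr_ivw(h, "mre")
    egger <- mr_egger(h)
    q <- cochran_q(h, fe$beta)
    primary <- select_primary(fe, mre, egger, q)
    data.frame(
      ivw_beta = fe$beta, ivw_se = fe$se,
      ivw_covered = fe$ci_low <= theta & theta <= fe$ci_high,
      primary_beta = primary$beta, primary_p = primary$pval,
      primary_covered = primary$ci_low <= theta & theta <= primary$ci_high,
      q_pval = q$pval, egger_beta = egger$beta,
      egger_intercept = egger$extra$intercept,
      egger_intercept_p = egger$extra$intercept_p,
      n_snps = nrow(h))
  })
  do.call(rbind, rows)
}

#' MR-PRESSO spike-in detection study
#'
#' For each replicate: simulate a clean triplet, harmonize, then offset
#' one SNP's outcome beta by `spike_multiplier` times its SE and run
#' [mr_presso()]. Records whether the spiked SNP had the smallest
#' outlier p-value and was flagged, and the global p.
#'
#' @param n_reps number of replicates.
#' @param config a [sim_config()].
#' @param spike_multiplier outcome-beta offset in SE units (default 10).
#' @param n_sim MR-PRESSO simulations per replicate (default 1000).
#' @param seed base seed.
#' @return Data frame per replicate: `top_outlier` (spiked SNP ranked
#'   first), `flagged`, `global_p`.
#' @export
presso_spikein_study <- function(n_reps, config = sim_config(theta_total = 0.2),
                                 spike_multiplier = 10, n_sim = 1000,
                                 seed = 1L) {
  rows <- lapply(seq_len(n_reps), function(r) {
    sim <- simulate_triplet(rep_config(config, seed, r))
    h <- harmonize(sim$exposure, sim$outcome)
    spike_at <- 1L + (r %% nrow(h))
    h$beta_out[spike_at] <- h$beta_out[spike_at] +
      spike_multiplier * h$se_out[spike_at]
    res <- mr_presso(h, n_sim = n_sim, seed = seed + 50000L + r)
    spiked <- h$snp[spike_at]
    data.frame(
      top_outlier = names(which.min(res$outlier_p)) == spiked,
      flagged = spiked %in% res$outliers,
      global_p = res$global_p)
  })
  do.call(rbind, rows)
}

#' Two-step mediation recovery study
#'
#' For each replicate: simulate a mediation triplet, estimate the three
#' legs by fixed-effect IVW (exposure legs on the exposure's
#' significant instruments; the mediator leg on mediator-significant
#' instruments excluding exposure-significant SNPs, i.e. disjoint
#' instrument sets), and decompose with [two_step_mediation()].
#'
#' @param n_reps number of replicates.
#' @param config a [sim_config()]; needs `n_snps_mediator > 0` for the
#'   mediator leg.
#' @param p_threshold instrument significance threshold (default 5e-6).
#' @param seed base seed.
#' @return Data frame per replicate: `a`, `b`, `c`, `proportion`,
#'   `ci_low`, `ci_high`, `covered` (CI contains the true proportion),
#'   `identity_gap` (|indirect + direct - c|), `pval`.
#' @export
mediation_recovery_study <- function(n_reps,
                                     config = sim_config(
                                       n_snps = 50, n_snps_mediator = 50,
                                       a_true = 0.5, b_true = 0.4,
                                       theta_total = 0.25),
                                     p_threshold = 5e-6, seed = 1L) {
  true_prop <- config$a_true * config$b_true / config$theta_total
  ivw_leg <- function(exposure, outcome, exclude = character(0)) {
    sig <- threshold_instruments(exposure, p_threshold)
    sig <- sig[!sig$snp %in% exclude, , drop = FALSE]
    mr_ivw(harmonize(sig, outcome), "fe")
  }
  rows <- lapply(seq_len(n_reps), function(r) {
    sim <- simulate_triplet(rep_config(config, seed, r))
    exp_sig <- threshold_instruments(sim$exposure, p_threshold)$snp
    a <- ivw_leg(sim$exposure, sim$mediator)
    b <- ivw_leg(sim$mediator, sim$outcome, exclude = exp_sig)
    cc <- ivw_leg(sim$exposure, sim$outcome)
    med <- two_step_mediation(a$beta, a$se, b$beta, b$se, cc$beta, cc$se)
    data.frame(
      a = a$beta, b = b$beta, c = cc$beta,
      proportion = med$proportion, ci_low = med$ci_low, ci_high = med$ci_high,
      covered = med$ci_low <= true_prop & true_prop <= med$ci_high,
      identity_gap = abs(med$indirect + med$direct - med$c),
      pval = med$pval)
  })
  do.call(rbind, rows)
}

#' Random-effects meta-analysis recovery study
#'
#' For each replicate: draw `k` cohort log-OR estimates around a common
#' true effect with between-cohort SD `tau` and within-cohort SE
#' `se_within`, then pool with [pool_random_effects()]. The
#' within-cohort SE defaults to 0.02 so that the between-cohort
#' component is identifiable with few cohorts (see the methods
#' vignette).
#'
#' @param n_reps number of replicates.
#' @param k cohorts per replicate (default 4).
#' @param true_beta common log-OR (default 0.15).
#' @param tau between-cohort SD (default 0.05).
#' @param se_within within-cohort SE (default 0.02).
#' @param seed base seed.
#' @return Data frame per replicate: `pooled`, `se`, `tau2`, `Q`,
#'   `covered` (random-effects CI contains `true_beta`).
#' @export
meta_recovery_study <- function(n_reps, k = 4, true_beta = 0.15, tau = 0.05,
                                se_within = 0.02, seed = 1L) {
  rows <- lapply(seq_len(n_reps), function(r) {
    with_seed(seed + r, {
      beta <- stats::rnorm(k, true_beta + stats::rnorm(k, 0, tau), se_within)
      m <- pool_random_effects(data.frame(beta = beta, se = rep(se_within, k)))
      data.frame(pooled = m$beta, se = m$se, tau2 = m$tau2, Q = m$Q,
                 covered = m$ci_low <= true_beta & true_beta <= m$ci_high)
    })
  })
  do.call(rbind, rows)
}
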
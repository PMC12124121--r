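#' Study-level configuration
#'
#' Bundles the thresholds and settings shared by every stage of the
#' screening workflow. Defaults follow the study design: exposure
#' instruments at p < 5e-6 (5e-8 in the reverse direction), LD clumping
#' at r2 < 0.001 within a 10,000 kb window, removal of SNPs associated
#' with the outcome at p < 5e-5, Steiger directionality filtering, and
#' MR-PRESSO outlier removal. Per-cohort significance for the screen is
#' the selected primary estimate's p < `alpha` with no multiplicity
#' correction; `p_adjust` exposes Bonferroni/FDR variants.
#'
#' @param p_exposure forward instrument threshold.
#' @param p_reverse reverse-direction instrument threshold.
#' @param clump_r2,clump_kb clumping parameters.
#' @param p_outcome outcome-association removal threshold.
#' @param palindrome_maf_limit see [harmonize()].
#' @param presso run MR-PRESSO outlier removal in selection.
#' @param presso_n_sim,outlier_alpha MR-PRESSO settings.
#' @param n_boot bootstrap replicates for median/mode estimators.
#' @param phi weighted-mode bandwidth multiplier.
#' @param alpha per-cohort significance level for flagging.
#' @param p_adjust multiplicity adjustment across exposures within a
#'   cohort: `"none"` (default), or any method of [stats::p.adjust()].
#' @param min_cohorts cohorts required for meta-analysis follow-up.
#' @return A list of class `study_config`.
#' @export
study_config <- function(p_exposure = 5e-6, p_reverse = 5e-8,
                         clump_r2 = 0.001, clump_kb = 10000,
                         p_outcome = 5e-5, palindrome_maf_limit = 0.42,
                         presso = TRUE, presso_n_sim = 1000,
                         outlier_alpha = 0.05, n_boot = 1000, phi = 1,
                         alpha = 0.05, p_adjust = "none", min_cohorts = 2L) {
  for (nm in c("p_exposure", "p_reverse", "clump_r2", "p_outcome", "alpha"))
    check_scalar(get(nm), nm, lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(min_cohorts, "min_cohorts", lower = 1)
  structure(list(p_exposure = p_exposure, p_reverse = p_reverse,
                 clump_r2 = clump_r2, clump_kb = clump_kb,
                 p_outcome = p_outcome,
                 palindrome_maf_limit = palindrome_maf_limit,
                 presso = isTRUE(presso), presso_n_sim = presso_n_sim,
                 outlier_alpha = outlier_alpha, n_boot = n_boot, phi = phi,
                 alpha = alpha, p_adjust = p_adjust,
                 min_cohorts = as.integer(min_cohorts)),
            class = "study_config")
}

#' Run one exposure-outcome MR analysis end to end
#'
#' Applies the instrument-selection chain ([select_instruments()]) and
#' the estimator suite ([mr_suite()]) to a single pair, returning a flat
#' result row plus the underlying objects. Pairs ending with fewer than
#' two instruments are reported with a status rather than an error.
#'
#' @param exposure,outcome [summary_stats()] objects.
#' @param ld optional [ld_matrix()].
#' @param config a [study_config()].
#' @param p_threshold instrument threshold; defaults to
#'   `config$p_exposure`.
#' @param exclude_snps SNP identifiers to exclude from the candidate
#'   instruments before selection (used by the mediation stage to keep
#'   the mediator's instrument set free of the upstream exposure's).
#' @param outcome_filter apply the outcome-association filter; disabled
#'   by the mediation stage's exposure-to-mediator leg, where a strong
#'   genuine instrument-mediator association is the point, not a red
#'   flag.
#' @param seed RNG seed threaded to MR-PRESSO and the bootstraps.
#' @return A list of class `mr_pair`: `row` (one-row data frame of the
#'   reporting columns), `suite`, `instruments` (the selected
#'   `harmonized_set` with provenance), `status`.
#' @export
mr_pair <- function(exposure, outcome, ld = NULL, config = study_config(),
                    p_threshold = NULL, exclude_snps = character(0),
                    outcome_filter = TRUE, seed = NULL) {
  stopifnot(inherits(config, "study_config"))
  p_threshold <- p_threshold %||% config$p_exposure
  if (length(exclude_snps))
    exposure <- exposure[!exposure$snp %in% exclude_snps, , drop = FALSE]
  hset <- select_instruments(
    exposure, outcome, ld = ld, p_threshold = p_threshold,
    clump_r2 = config$clump_r2, clump_kb = config$clump_kb,
    p_outcome = config$p_outcome, outcome_filter = outcome_filter,
    steiger = TRUE, presso = config$presso,
    presso_n_sim = config$presso_n_sim, outlier_alpha = config$outlier_alpha,
    seed = seed, palindrome_maf_limit = config$palindrome_maf_limit)
  suite <- mr_suite(hset, n_boot = config$n_boot, phi = config$phi,
                    seed = if (is.null(seed)) NULL else seed + 2L)
  presso_res <- attr(hset, "presso")
  est <- suite$primary
  egger <- suite$estimates$egger
  row <- data.frame(
    exposure = attr(hset, "exposure_id"), outcome = attr(hset, "outcome_id"),
    status = suite$status, method = if (is.null(est)) NA_character_ else est$method,
    n_snps = suite$n_snps,
    beta = if (is.null(est)) NA_real_ else est$beta,
    se = if (is.null(est)) NA_real_ else est$se,
    or = if (is.null(est)) NA_real_ else exp(est$beta),
    or_ci_low = if (is.null(est)) NA_real_ else exp(est$ci_low),
    or_ci_high = if (is.null(est)) NA_real_ else exp(est$ci_high),
    pval = if (is.null(est)) NA_real_ else est$pval,
    q = if (is.null(suite$q)) NA_real_ else suite$q$Q,
    q_pval = if (is.null(suite$q)) NA_real_ else suite$q$pval,
    egger_intercept = if (is.null(egger)) NA_real_ else egger$extra$intercept,
    egger_intercept_p = if (is.null(egger)) NA_real_ else egger$extra$intercept_p,
    presso_global_p = if (is.null(presso_res)) NA_real_ else presso_res$global_p,
    f_mean = if (nrow(hset)) mean(f_statistic(hset)) else NA_real_,
    stringsAsFactors = FALSE)
  structure(list(row = row, suite = suite, instruments = hset, status = suite$status),
            class = "mr_pair")
}

#' Forward screen of exposures across outcome cohorts
#'
#' Runs [mr_pair()] for every exposure x cohort combination and flags
#' per-cohort significance of the selected primary estimate. The
#' screening table is the tabular analogue of a lipid-by-cohort
#' association figure.
#'
#' @param exposures named list of [summary_stats()] exposures.
#' @param cohorts named list of [summary_stats()] outcome cohorts.
#' @param ld optional [ld_matrix()] shared by all exposures.
#' @param config a [study_config()].
#' @param seed base seed; each pair derives its own as
#'   `seed + pair index`.
#' @return A data frame of class `screen_result`: one row per pair with
#'   the [mr_pair()] reporting columns, a `cohort` column, a
#'   `significant` flag and `n_cohorts_significant` per exposure.
#' @export
run_forward_screen <- function(exposures, cohorts, ld = NULL,
                               config = study_config(), seed = 1L) {
  stopifnot(inherits(config, "study_config"))
  if (!length(exposures)) {
    warning("empty exposure list; nothing to screen", call. = FALSE)
    return(structure(data.frame(), class = c("screen_result", "data.frame")))
  }
  exposures <- name_list(exposures, "exposure")
  cohorts <- name_list(cohorts, "cohort")
  rows <- list()
  i <- 0L
  for (ex in names(exposures)) {
    for (co in names(cohorts)) {
      i <- i + 1L
      pr <- mr_pair(exposures[[ex]], cohorts[[co]], ld = ld, config = config,
                    seed = if (is.null(seed)) NULL else seed + i)
      row <- pr$row
      row$exposure <- ex
      row$cohort <- co
      rows[[i]] <- row
    }
  }
  out <- do.call(rbind, rows)
  padj <- stats::ave(out$pval, out$cohort,
                     FUN = function(p) stats::p.adjust(p, method = config$p_adjust))
  out$significant <- !is.na(padj) & padj < config$alpha
  out$n_cohorts_significant <-
    stats::ave(as.integer(out$significant), out$exposure, FUN = sum)
  rownames(out) <- NULL
  structure(out, class = c("screen_result", "data.frame"))
}

name_list <- function(x, prefix) {
  if (is.null(names(x)) || any(names(x) == ""))
    names(x) <- vapply(seq_along(x), function(i)
      attr(x[[i]], "trait_id") %||% sprintf("%s_%d", prefix, i), "")
  x
}

#' Exposures significant in multiple cohorts
#'
#' @param screen a [run_forward_screen()] result.
#' @param min_cohorts minimum number of cohorts in which the exposure's
#'   primary estimate was significant (default 2).
#' @return Character vector of exposure names.
#' @export
select_multi_cohort <- function(screen, min_cohorts = 2L) {
  stopifnot(inherits(screen, "screen_result"))
  check_scalar(min_cohorts, "min_cohorts", lower = 1)
  if (!nrow(screen)) return(character(0))
  counts <- tapply(screen$significant, screen$exposure, sum)
  names(counts)[counts >= min_cohorts]
}

#' Meta-analyse a screened exposure across cohorts
#'
#' Pools the per-cohort primary estimates of one exposure from a screen
#' table with [pool_random_effects()].
#'
#' @param screen a [run_forward_screen()] result.
#' @param exposure exposure name present in `screen`.
#' @return A [pool_random_effects()] result.
#' @export
meta_analyse_exposure <- function(screen, exposure) {
  stopifnot(inherits(screen, "screen_result"))
  rows <- screen[screen$exposure == exposure & screen$status %in% c("ok", "single_snp") &
                   is.finite(screen$beta), , drop = FALSE]
  if (nrow(rows) < 2L)
    stop(sprintf("exposure '%s' has fewer than 2 usable cohort estimates", exposure),
         call. = FALSE)
  pool_random_effects(data.frame(cohort = rows$cohort, beta = rows$beta,
                                 se = rows$se, stringsAsFactors = FALSE))
}

#' Reverse-direction MR
#'
#' Treats each outcome cohort as the exposure (instrumented at the
#' stricter reverse threshold, 5e-8 by default) and each lipid as the
#' outcome, probing reverse causation for the lipids that survived the
#' forward screen.
#'
#' @param cohorts named list of [summary_stats()] (disease GWAS, now
#'   exposures).
#' @param lipids named list of [summary_stats()] (lipids, now outcomes).
#' @param ld optional [ld_matrix()].
#' @param config a [study_config()]; `config$p_reverse` is the
#'   instrument threshold.
#' @param seed base seed as in [run_forward_screen()].
#' @return Data frame with one row per cohort x lipid pair, in the same
#'   layout as the forward screen.
#' @export
run_reverse <- function(cohorts, lipids, ld = NULL, config = study_config(),
                        seed = 1L) {
  stopifnot(inherits(config, "study_config"))
  cohorts <- name_list(cohorts, "cohort")
  lipids <- name_list(lipids, "lipid")
  rows <- list()
  i <- 0L
  for (co in names(cohorts)) {
    for (li in names(lipids)) {
      i <- i + 1L
      pr <- mr_pair(cohorts[[co]], lipids[[li]], ld = ld, config = config,
                    p_threshold = config$p_reverse,
                    seed = if (is.null(seed)) NULL else seed + i)
      row <- pr$row
      row$exposure <- co
      row$outcome <- li
      rows[[i]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-step mediation stage
#'
#' For each cholesterol exposure and each mediating lipid: estimates the
#' total effect `c` (exposure to outcome), the first step `a` (exposure
#' to mediator) and the second step `b` (mediator to outcome) by
#' separate MR fits, then decomposes them with [two_step_mediation()].
#' By default the mediator's instrument set excludes SNPs that reach the
#' exposure's instrument threshold in the exposure GWAS, so `b` is not
#' contaminated by the exposure's direct path (plain two-step MR with
#' disjoint instruments; no multivariable adjustment).
#'
#' @param exposures named list of cholesterol [summary_stats()].
#' @param mediators named list of lipid [summary_stats()].
#' @param outcome one outcome cohort [summary_stats()].
#' @param ld optional [ld_matrix()].
#' @param config a [study_config()].
#' @param exclude_exposure_snps drop exposure-significant SNPs from the
#'   mediator instrument sets (default `TRUE`).
#' @param seed base seed.
#' @return Data frame with one row per exposure x mediator pair:
#'   `mediator`, `exposure`, `outcome`, the `a`, `b`, `c` legs with SEs
#'   and instrument counts, `proportion_pct`, `ci_low_pct`,
#'   `ci_high_pct`, `pval`, and a `status` (`"ok"` or the reason no
#'   proportion is reported).
#' @export
run_mediation_stage <- function(exposures, mediators, outcome, ld = NULL,
                                config = study_config(),
                                exclude_exposure_snps = TRUE, seed = 1L) {
  stopifnot(inherits(config, "study_config"), inherits(outcome, "summary_stats"))
  exposures <- name_list(exposures, "exposure")
  mediators <- name_list(mediators, "mediator")
  rows <- list()
  i <- 0L
  for (ex in names(exposures)) {
    c_fit <- mr_pair(exposures[[ex]], outcome, ld = ld, config = config,
                     seed = if (is.null(seed)) NULL else seed + 1000L)
    a_seed_base <- if (is.null(seed)) NULL else seed + 2000L
    for (md in names(mediators)) {
      i <- i + 1L
      a_fit <- mr_pair(exposures[[ex]], mediators[[md]], ld = ld, config = config,
                       outcome_filter = FALSE,
                       seed = if (is.null(a_seed_base)) NULL else a_seed_base + i)
      excl <- character(0)
      if (exclude_exposure_snps) {
        sig_exp <- threshold_instruments(exposures[[ex]], config$p_exposure)
        excl <- sig_exp$snp
      }
      b_fit <- mr_pair(mediators[[md]], outcome, ld = ld, config = config,
                       exclude_snps = excl,
                       seed = if (is.null(seed)) NULL else seed + 3000L + i)
      rows[[i]] <- mediation_row(ex, md, attr(outcome, "trait_id"),
                                 a_fit, b_fit, c_fit)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

mediation_row <- function(exposure, mediator, outcome, a_fit, b_fit, c_fit) {
  base <- data.frame(
    mediator = mediator, exposure = exposure, outcome = outcome,
    a = NA_real_, se_a = NA_real_, n_snps_a = a_fit$suite$n_snps,
    b = NA_real_, se_b = NA_real_, n_snps_b = b_fit$suite$n_snps,
    c = NA_real_, se_c = NA_real_, n_snps_c = c_fit$suite$n_snps,
    indirect = NA_real_, direct = NA_real_, proportion_pct = NA_real_,
    ci_low_pct = NA_real_, ci_high_pct = NA_real_, pval = NA_real_,
    status = "ok", stringsAsFactors = FALSE)
  fits <- list(a = a_fit, b = b_fit, c = c_fit)
  missing <- names(fits)[vapply(fits, function(f) is.null(f$suite$primary), TRUE)]
  if (length(missing)) {
    base$status <- paste0("insufficient instruments for ",
                          paste(missing, collapse = ", "))
    return(base)
  }
  a <- a_fit$suite$primary; b <- b_fit$suite$primary; cc <- c_fit$suite$primary
  base$a <- a$beta; base$se_a <- a$se
  base$b <- b$beta; base$se_b <- b$se
  base$c <- cc$beta; base$se_c <- cc$se
  med <- tryCatch(
    two_step_mediation(a$beta, a$se, b$beta, b$se, cc$beta, cc$se),
    error = function(e) NULL)
  if (is.null(med)) {
    base$status <- "total effect ~ 0, proportion undefined"
    return(base)
  }
  base$indirect <- med$indirect
  base$direct <- med$direct
  base$proportion_pct <- 100 * med$proportion
  base$ci_low_pct <- 100 * med$ci_low
  base$ci_high_pct <- 100 * med$ci_high
  base$pval <- med$pval
  base
}
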
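#' Instrument selection and filtering
#'
#' Functions implementing the instrument-selection chain used throughout
#' the workflow: exposure p-value thresholding, greedy LD clumping,
#' removal of outcome-associated SNPs, Steiger directionality filtering,
#' and the per-SNP F statistic as a strength diagnostic.
#'
#' @name instruments
NULL

#' Keep SNPs below an exposure p-value threshold
#'
#' @param stats a [summary_stats()] object.
#' @param p_threshold strict upper bound on `pval`; SNPs with
#'   `pval < p_threshold` are retained. The forward lipid screen uses
#'   5e-6, the reverse direction 5e-8.
#' @return The retained subset, still a `summary_stats`.
#' @export
threshold_instruments <- function(stats, p_threshold) {
  stopifnot(inherits(stats, "summary_stats"))
  check_scalar(p_threshold, "p_threshold", lower = 0, upper = 1,
               strict_lower = TRUE)
  stats[stats$pval < p_threshold, , drop = FALSE]
}

#' Pairwise LD matrix
#'
#' Validates a symmetric matrix of pairwise r-squared values with unit
#' diagonal, indexed by SNP identifier.
#'
#' @param r2 square numeric matrix.
#' @param snp_ids SNP identifiers; defaults to the matrix dimnames.
#' @return The matrix with class `ld_matrix`.
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(snp_ids)) stop("snp_ids required (or matrix dimnames)", call. = FALSE)
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(snp_ids))
    stop("LD matrix must be square and match snp_ids", call. = FALSE)
  dimnames(r2) <- list(snp_ids, snp_ids)
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1))
    stop("LD r-squared values must lie in [0, 1]", call. = FALSE)
  if (max(abs(r2 - t(r2))) > 1e-8) stop("LD matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("LD matrix diagonal must be 1", call. = FALSE)
  structure(r2, class = c("ld_matrix", "matrix", "array"))
}

#' Read / write an LD matrix as TSV
#'
#' The on-disk format is a square tab-separated table whose header row
#' and first column both carry the SNP identifiers.
#'
#' @param path file path.
#' @return [read_ld_matrix()] returns an [ld_matrix()];
#'   [write_ld_matrix()] returns `path` invisibly.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  ld_matrix(as.matrix(raw))
}

#' @param ld an [ld_matrix()].
#' @rdname read_ld_matrix
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  utils::write.table(unclass(ld), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Greedy LD clumping
#'
#' Prunes correlated instruments the way PLINK-style clumping does:
#' candidates are ordered by ascending p-value (ties broken by SNP
#' identifier for determinism); the best remaining SNP is accepted as an
#' index SNP and every remaining SNP on the same chromosome within
#' `window_kb` of it with `r2 >= r2_threshold` is removed; repeat until
#' exhausted. Only index SNPs are returned.
#'
#' @param stats a [summary_stats()] object.
#' @param ld an [ld_matrix()] covering (a subset of) the SNPs; pairs
#'   absent from it are treated as unlinked.
#' @param r2_threshold LD ceiling between retained SNPs (default 0.001).
#' @param window_kb clumping window in kilobases (default 10000).
#' @return The index-SNP subset of `stats`, in the original row order,
#'   with attribute `ld_missing` naming SNPs absent from `ld`.
#' @export
clump <- function(stats, ld = NULL, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(stats, "summary_stats"))
  check_scalar(r2_threshold, "r2_threshold", lower = 0, upper = 1)
  check_scalar(window_kb, "window_kb", lower = 0, strict_lower = TRUE)
  if (nrow(stats) <= 1L) return(stats)
  d <- as.data.frame(stats)
  ord <- order(d$pval, d$snp)
  missing_ld <- character(0)
  if (!is.null(ld)) {
    stopifnot(inherits(ld, "ld_matrix"))
    missing_ld <- setdiff(d$snp, rownames(ld))
  } else {
    missing_ld <- d$snp
  }
  r2_of <- function(a, b) {
    # pairwise r2, 0 (unlinked) when either SNP is absent from the panel
    out <- numeric(length(b))
    if (!is.null(ld) && a %in% rownames(ld)) {
      hit <- b %in% colnames(ld)
      out[hit] <- ld[a, b[hit]]
    }
    out
  }
  avail <- rep(TRUE, nrow(d))
  index_snps <- character(0)
  for (i in ord) {
    if (!avail[i]) next
    index_snps <- c(index_snps, d$snp[i])
    avail[i] <- FALSE
    j <- which(avail)
    if (!length(j)) break
    conflict <- d$chr[j] == d$chr[i] &
      abs(d$pos[j] - d$pos[i]) <= window_kb * 1000 &
      r2_of(d$snp[i], d$snp[j]) >= r2_threshold
    avail[j[conflict]] <- FALSE
  }
  out <- stats[stats$snp %in% index_snps, , drop = FALSE]
  attr(out, "ld_missing") <- missing_ld
  out
}

#' Remove SNPs associated with the outcome
#'
#' Drops harmonized SNPs whose outcome association (two-sided normal
#' p-value recomputed from `beta_out / se_out`) falls below
#' `p_threshold`, the guard against instruments acting on the outcome
#' directly. The screen uses 5e-5.
#'
#' @param hset a [harmonize()]d set.
#' @param p_threshold strict removal threshold.
#' @return The retained subset with attribute `dropped_outcome`
#'   naming removed SNPs.
#' @export
filter_outcome_associated <- function(hset, p_threshold = 5e-5) {
  stopifnot(inherits(hset, "harmonized_set"))
  check_scalar(p_threshold, "p_threshold", lower = 0, upper = 1,
               strict_lower = TRUE)
  p_out <- two_sided_p(hset$beta_out / hset$se_out)
  drop <- p_out < p_threshold
  out <- hset[!drop, , drop = FALSE]
  attr(out, "dropped_outcome") <- hset$snp[drop]
  out
}

#' Steiger directionality filter
#'
#' Removes SNPs that explain more variance in the outcome than in the
#' exposure, i.e. instruments whose primary association is plausibly
#' with the outcome. Variance explained is approximated per trait as
#' `t^2 / (t^2 + n - 2)` with `t = beta / se`; a SNP is dropped when the
#' outcome r-squared strictly exceeds the exposure r-squared
#' (log-odds-scale outcomes are treated as continuous for this purpose).
#'
#' @param hset a [harmonize()]d set carrying `n_exp` / `n_out` columns.
#' @param n_exp,n_out optional sample-size overrides (scalars).
#' @return The retained subset with attribute `dropped_steiger`.
#' @export
steiger_filter <- function(hset, n_exp = NULL, n_out = NULL) {
  stopifnot(inherits(hset, "harmonized_set"))
  n_e <- n_exp %||% hset$n_exp
  n_o <- n_out %||% hset$n_out
  if (any(n_e <= 2) || any(n_o <= 2))
    stop("Steiger filtering needs sample sizes > 2", call. = FALSE)
  r2_of <- function(beta, se, n) {
    t2 <- (beta / se)^2
    t2 / (t2 + n - 2)
  }
  drop <- r2_of(hset$beta_out, hset$se_out, n_o) >
    r2_of(hset$beta_exp, hset$se_exp, n_e)
  out <- hset[!drop, , drop = FALSE]
  attr(out, "dropped_steiger") <- hset$snp[drop]
  out
}

#' Per-SNP instrument-strength F statistic
#'
#' The conventional single-SNP approximation `(beta_exp / se_exp)^2`.
#' Reported as a diagnostic; no F cutoff is applied anywhere in the
#' selection chain.
#'
#' @param hset a [harmonize()]d set.
#' @return Named numeric vector of F statistics, one per SNP.
#' @export
f_statistic <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  stats::setNames((hset$beta_exp / hset$se_exp)^2, hset$snp)
}

#' Run the full instrument-selection chain
#'
#' Applies, in order: exposure p-value thresholding, LD clumping,
#' harmonization against the outcome, outcome-association filtering,
#' Steiger directionality filtering, and (when at least four SNPs
#' remain) MR-PRESSO outlier removal. Provenance flags for every
#' candidate SNP are retained so that dropped + retained partition the
#' candidates exactly.
#'
#' @param exposure,outcome [summary_stats()] objects.
#' @param ld optional [ld_matrix()]; `NULL` treats all SNPs as unlinked.
#' @param p_threshold exposure significance threshold (default 5e-6).
#' @param clump_r2,clump_kb clumping parameters (defaults 0.001, 10000).
#' @param p_outcome outcome-association removal threshold (default 5e-5).
#' @param outcome_filter apply the outcome-association filter (default
#'   `TRUE`); disable for continuous downstream traits where a strong
#'   genuine association with the "outcome" is expected (e.g. the
#'   exposure-to-mediator leg of a mediation analysis).
#' @param steiger apply the Steiger filter (default `TRUE`).
#' @param presso apply MR-PRESSO outlier removal (default `TRUE`).
#' @param presso_n_sim,outlier_alpha,seed MR-PRESSO settings, see
#'   [mr_presso()].
#' @param palindrome_maf_limit passed to [harmonize()].
#' @return The final `harmonized_set` with attributes `provenance`
#'   (a data frame with one row per candidate SNP and the flags
#'   `passed_p`, `clump_index`, `action`, `outcome_filtered`,
#'   `steiger_dropped`, `presso_dropped`, `retained`, `f_stat`) and
#'   `presso` (the [mr_presso()] result or `NULL`).
#' @export
select_instruments <- function(exposure, outcome, ld = NULL,
                               p_threshold = 5e-6, clump_r2 = 0.001,
                               clump_kb = 10000, p_outcome = 5e-5,
                               outcome_filter = TRUE,
                               steiger = TRUE, presso = TRUE,
                               presso_n_sim = 1000, outlier_alpha = 0.05,
                               seed = NULL, palindrome_maf_limit = 0.42) {
  stopifnot(inherits(exposure, "summary_stats"))
  prov <- data.frame(snp = exposure$snp, passed_p = FALSE, clump_index = FALSE,
                     action = NA_character_, outcome_filtered = FALSE,
                     steiger_dropped = FALSE, presso_dropped = FALSE,
                     retained = FALSE, f_stat = NA_real_,
                     stringsAsFactors = FALSE)
  sig <- threshold_instruments(exposure, p_threshold)
  prov$passed_p <- prov$snp %in% sig$snp
  if (nrow(sig) == 0L) return(empty_selection(exposure, outcome, prov))

  idx <- clump(sig, ld = ld, r2_threshold = clump_r2, window_kb = clump_kb)
  prov$clump_index <- prov$snp %in% idx$snp

  shared <- intersect(idx$snp, outcome$snp)
  if (!length(shared)) return(empty_selection(exposure, outcome, prov))
  h <- harmonize(idx, outcome, palindrome_maf_limit = palindrome_maf_limit)
  log <- attr(h, "action_log")
  prov$action[match(log$snp, prov$snp)] <- log$action

  if (outcome_filter) {
    h2 <- filter_outcome_associated(h, p_outcome)
    prov$outcome_filtered <- prov$snp %in% attr(h2, "dropped_outcome")
  } else h2 <- h
  if (steiger && nrow(h2) > 0L) {
    h3 <- steiger_filter(h2)
    prov$steiger_dropped <- prov$snp %in% attr(h3, "dropped_steiger")
  } else h3 <- h2

  presso_res <- NULL
  if (presso && nrow(h3) >= 4L) {
    presso_res <- mr_presso(h3, n_sim = presso_n_sim,
                            outlier_alpha = outlier_alpha, seed = seed)
    if (length(presso_res$outliers)) {
      prov$presso_dropped <- prov$snp %in% presso_res$outliers
      h3 <- h3[!h3$snp %in% presso_res$outliers, , drop = FALSE]
    }
  }
  prov$retained <- prov$snp %in% h3$snp
  f <- f_statistic(h3)
  prov$f_stat[match(names(f), prov$snp)] <- f
  attr(h3, "provenance") <- prov
  attr(h3, "presso") <- presso_res
  h3
}

empty_selection <- function(exposure, outcome, prov) {
  h <- harmonized_from_vectors(numeric(0), numeric(0), numeric(0), numeric(0),
                               snp = character(0))
  attr(h, "exposure_id") <- attr(exposure, "trait_id")
  attr(h, "outcome_id") <- attr(outcome, "trait_id")
  attr(h, "outcome_type") <- attr(outcome, "trait_type")
  attr(h, "provenance") <- prov
  h
}
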
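#' Harmonize exposure and outcome summary statistics
#'
#' Aligns two summary-statistics tables to a common effect allele, the
#' prerequisite for any two-sample MR fit. SNPs are intersected on their
#' identifier; for each shared SNP the outcome record is brought onto the
#' exposure's allele coding:
#'
#' * matching coding: kept unchanged (`none`);
#' * same alleles on the complementary strand: strand complemented
#'   (`flipped`, no sign change);
#' * effect/other alleles swapped (on either strand): outcome beta is
#'   negated and its allele frequency complemented (`swapped`);
#' * palindromic pairs (A/T or C/G), where allele labels cannot resolve
#'   strand: orientation is inferred from allele frequencies when both
#'   traits' minor-allele frequencies are below `palindrome_maf_limit`
#'   (aligned if both effect-allele frequencies fall on the same side of
#'   0.5, otherwise `swapped`), and the SNP is dropped
#'   (`dropped_palindromic`) when frequencies are too close to 0.5 to
#'   call;
#' * allele pairs that cannot be reconciled at all are dropped
#'   (`dropped_mismatch`).
#'
#' @param exposure,outcome [summary_stats()] objects.
#' @param palindrome_maf_limit minor-allele-frequency ceiling below which
#'   a palindromic SNP's orientation is trusted to the frequencies;
#'   default 0.42.
#'
#' @return A data frame of class `harmonized_set` with one row per
#'   retained SNP: `snp`, `chr`, `pos`, `ea`, `oa`, `eaf` (exposure
#'   scale), `beta_exp`, `se_exp`, `pval_exp`, `n_exp`, `eaf_out`,
#'   `beta_out`, `se_out`, `pval_out`, `n_out`, `action`. The attribute
#'   `action_log` records the action for every intersected SNP including
#'   dropped ones, and `exposure_id` / `outcome_id` / `outcome_type`
#'   carry the trait labels.
#' @export
harmonize <- function(exposure, outcome, palindrome_maf_limit = 0.42) {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  check_scalar(palindrome_maf_limit, "palindrome_maf_limit", lower = 0, upper = 0.5)
  if (nrow(exposure) == 0L || nrow(outcome) == 0L)
    stop("cannot harmonize empty summary statistics", call. = FALSE)
  m <- merge(as.data.frame(exposure), as.data.frame(outcome), by = "snp",
             suffixes = c("_exp", "_out"), sort = TRUE)
  if (nrow(m) == 0L)
    stop(sprintf("no shared SNPs between '%s' and '%s'",
                 attr(exposure, "trait_id"), attr(outcome, "trait_id")),
         call. = FALSE)

  comp <- function(a) unname(DNA_COMPLEMENT[a])
  pal <- m$ea_exp == comp(m$oa_exp)
  same <- m$ea_out == m$ea_exp & m$oa_out == m$oa_exp
  swapped <- m$ea_out == m$oa_exp & m$oa_out == m$ea_exp
  strand <- comp(m$ea_out) == m$ea_exp & comp(m$oa_out) == m$oa_exp
  strand_swapped <- comp(m$ea_out) == m$oa_exp & comp(m$oa_out) == m$ea_exp

  action <- rep("dropped_mismatch", nrow(m))
  action[!pal & same] <- "none"
  action[!pal & strand] <- "flipped"
  action[!pal & (swapped | strand_swapped)] <- "swapped"

  # palindromic: any coding of the same pair is label-ambiguous; decide by
  # frequency or drop when both frequencies hug 0.5
  pal_pair <- pal & (same | swapped)
  maf_ok <- pmin(m$eaf_exp, 1 - m$eaf_exp) < palindrome_maf_limit &
    pmin(m$eaf_out, 1 - m$eaf_out) < palindrome_maf_limit
  aligned <- (m$eaf_exp < 0.5) == (m$eaf_out < 0.5)
  action[pal_pair & !maf_ok] <- "dropped_palindromic"
  action[pal_pair & maf_ok & aligned] <- "none"
  action[pal_pair & maf_ok & !aligned] <- "swapped"

  flip <- action == "swapped"
  m$beta_out[flip] <- -m$beta_out[flip]
  m$eaf_out[flip] <- 1 - m$eaf_out[flip]

  keep <- action %in% c("none", "flipped", "swapped")
  out <- data.frame(
    snp = m$snp, chr = m$chr_exp, pos = m$pos_exp,
    ea = m$ea_exp, oa = m$oa_exp, eaf = m$eaf_exp,
    beta_exp = m$beta_exp, se_exp = m$se_exp, pval_exp = m$pval_exp,
    n_exp = m$n_exp, eaf_out = m$eaf_out, beta_out = m$beta_out,
    se_out = m$se_out, pval_out = m$pval_out, n_out = m$n_out,
    action = action, stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            exposure_id = attr(exposure, "trait_id"),
            outcome_id = attr(outcome, "trait_id"),
            outcome_type = attr(outcome, "trait_type"),
            palindrome_maf_limit = palindrome_maf_limit,
            action_log = data.frame(snp = m$snp, action = action,
                                    stringsAsFactors = FALSE),
            class = c("harmonized_set", "data.frame"))
}

#' @export
`[.harmonized_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("beta_exp", "se_exp", "beta_out", "se_out") %in% names(out))) {
    for (a in c("exposure_id", "outcome_id", "outcome_type", "palindrome_maf_limit", "action_log"))
      attr(out, a) <- attr(x, a)
    class(out) <- c("harmonized_set", "data.frame")
    rownames(out) <- NULL
  }
  out
}

#' @export
print.harmonized_set <- function(x, ...) {
  log <- attr(x, "action_log")
  cat(sprintf("Harmonized set: %s -> %s, %d/%d SNPs retained\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"),
              nrow(x), if (is.null(log)) nrow(x) else nrow(log)))
  if (!is.null(log)) print(table(log$action))
  invisible(x)
}

#' Build a harmonized set from aligned effect vectors
#'
#' Constructs a `harmonized_set` directly from already-aligned exposure
#' and outcome effects, bypassing allele bookkeeping. Intended for
#' estimator-level work (simulation studies, oracle comparisons) where
#' the allele layer is irrelevant.
#'
#' @param beta_exp,se_exp,beta_out,se_out numeric vectors of equal length.
#' @param snp optional SNP identifiers; generated when `NULL`.
#' @param n_exp,n_out nominal sample sizes recorded on the rows.
#' @return A `harmonized_set` as produced by [harmonize()].
#' @export
harmonized_from_vectors <- function(beta_exp, se_exp, beta_out, se_out,
                                    snp = NULL, n_exp = 1e5, n_out = 1e5) {
  k <- length(beta_exp)
  stopifnot(length(se_exp) == k, length(beta_out) == k, length(se_out) == k)
  if (is.null(snp)) snp <- sprintf("rs%06d", seq_len(k))
  structure(data.frame(
    snp = snp, chr = rep_len("1", k), pos = seq_len(k),
    ea = rep_len("A", k), oa = rep_len("G", k),
    eaf = rep_len(0.3, k), beta_exp = beta_exp, se_exp = se_exp,
    pval_exp = two_sided_p(beta_exp / se_exp), n_exp = rep_len(n_exp, k),
    eaf_out = rep_len(0.3, k), beta_out = beta_out, se_out = se_out,
    pval_out = two_sided_p(beta_out / se_out), n_out = rep_len(n_out, k),
    action = rep_len("none", k), stringsAsFactors = FALSE
  ),
  exposure_id = "exposure", outcome_id = "outcome", outcome_type = "binary",
  class = c("harmonized_set", "data.frame"))
}
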
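# Small fixtures built in code, shared across test files.

# Minimal well-formed summary-stats data frame.
toy_stats_df <- function(k = 3, seed = 42) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    beta <- rnorm(k, 0, 0.1)
    se <- runif(k, 0.01, 0.05)
    data.frame(
      snp = sprintf("rs%03d", seq_len(k)),
      chr = as.character(sample(1:22, k, replace = TRUE)),
      pos = sample.int(1e8, k),
      ea = rep_len(c("A", "C", "G"), k),
      oa = rep_len(c("G", "T", "A"), k),
      eaf = runif(k, 0.1, 0.45),
      beta = beta, se = se,
      pval = 2 * pnorm(-abs(beta / se)),
      n = 50000, stringsAsFactors = FALSE)
  })
}

toy_stats <- function(k = 3, seed = 42, trait_id = "trait",
                      trait_type = "continuous") {
  summary_stats(toy_stats_df(k, seed), trait_id, trait_type)
}

# Harmonized set with prescribed ratio structure: beta_out = theta * beta_exp
# (+ optional per-SNP offsets), exact unless noise is added by the caller.
ratio_hset <- function(beta_exp, theta = 0.2, se_out = 0.05, se_exp = 0.01,
                       offset = 0) {
  harmonized_from_vectors(beta_exp, rep_len(se_exp, length(beta_exp)),
                          theta * beta_exp + offset,
                          rep_len(se_out, length(beta_exp)))
}

# Rebuild an outcome summary_stats from a harmonized set, in the exposure's
# allele coding (used to check harmonization idempotence).
stats_from_harmonized <- function(h, trait_id = "outcome_h") {
  summary_stats(data.frame(
    snp = h$snp, chr = h$chr, pos = h$pos, ea = h$ea, oa = h$oa,
    eaf = h$eaf_out, beta = h$beta_out, se = h$se_out, pval = h$pval_out,
    n = h$n_out, stringsAsFactors = FALSE), trait_id, "binary")
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
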
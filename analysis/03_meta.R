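#!/usr/bin/env Rscript
# Stage 3: random-effects meta-analysis of the multi-cohort lipids.
#
# Pools the per-cohort primary estimates (log-OR scale) of every lipid
# that was significant in >= 2 cohorts, DerSimonian-Laird. Writes
# results/meta.tsv and a per-lipid forest table under
# results/forest_<lipid>.tsv.

library(lipidmr)

screen <- read.delim("results/screen.tsv", stringsAsFactors = FALSE)
class(screen) <- c("screen_result", "data.frame")
hits <- select_multi_cohort(screen, min_cohorts = 2)
if (!length(hits)) stop("no multi-cohort lipids to pool")

rows <- lapply(hits, function(lip) {
  m <- meta_analyse_exposure(screen, lip)
  ft <- forest_table(m)
  write.table(ft, sprintf("results/forest_%s.tsv", lip), sep = "\t",
              quote = FALSE, row.names = FALSE)
  data.frame(exposure = lip, k = m$k, or = exp(m$beta),
             or_ci_low = exp(m$ci_low), or_ci_high = exp(m$ci_high),
             pval = m$pval, tau2 = m$tau2, Q = m$Q, q_pval = m$q_pval,
             I2 = m$I2, stringsAsFactors = FALSE)
})
meta <- do.call(rbind, rows)
write.table(meta, "results/meta.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (i in seq_len(nrow(meta)))
  cat(sprintf("%s: pooled OR %.3f (95%% CI %.3f-%.3f), p = %.3g, tau2 = %.4f\n",
              meta$exposure[i], meta$or[i], meta$or_ci_low[i],
              meta$or_ci_high[i], meta$pval[i], meta$tau2[i]))
cat("wrote results/meta.tsv and per-lipid forest tables\n")
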
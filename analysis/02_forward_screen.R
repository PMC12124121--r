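#!/usr/bin/env Rscript
# Stage 2: forward MR screen of every lipid against every CRC cohort.
#
# For each pair: instruments at p < 5e-6, LD clumping (all panels are
# LD-free here, so clumping is the identity), harmonization, removal of
# outcome-associated SNPs (p < 5e-5), Steiger directionality filtering,
# MR-PRESSO outlier removal, then the estimator suite with the
# primary-selection rule. Writes results/screen.tsv.

library(lipidmr)

data_dir <- "results/data"
lipid_files <- list.files(data_dir, pattern = "^lipid_.*\\.tsv$",
                          full.names = TRUE)
stopifnot(length(lipid_files) > 0)
exposures <- lapply(lipid_files, read_summary_stats)
names(exposures) <- sub("\\.tsv$", "", basename(lipid_files))
cohort_files <- list.files(data_dir, pattern = "^cohort.*\\.tsv$",
                           full.names = TRUE)
cohorts <- lapply(cohort_files, read_summary_stats, trait_type = "binary")
names(cohorts) <- sub("\\.tsv$", "", basename(cohort_files))

cfg <- study_config(n_boot = 500)
screen <- run_forward_screen(exposures, cohorts, config = cfg, seed = 7L)
write.table(screen, "results/screen.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

hits <- select_multi_cohort(screen, min_cohorts = 2)
sig_any <- unique(screen$exposure[screen$significant])
cat(sprintf("screened %d lipids x %d cohorts (%d pairs)\n",
            length(exposures), length(cohorts), nrow(screen)))
cat(sprintf("%d lipid(s) significant in at least one cohort: %s\n",
            length(sig_any), paste(sort(sig_any), collapse = ", ")))
cat(sprintf("%d lipid(s) significant in >= 2 cohorts (carried forward): %s\n",
            length(hits), paste(sort(hits), collapse = ", ")))
cat("wrote results/screen.tsv\n")
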
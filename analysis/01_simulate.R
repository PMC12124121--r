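#!/usr/bin/env Rscript
# Stage 1: build the synthetic study inputs.
#
# Ten lipid species are screened against four colorectal-cancer cohorts.
# Each lipid gets its own 80-SNP panel (40 instruments of its own plus 40
# decoy SNPs wired through the generator's mediator slot with zero
# effects); lipids 1 and 2 are truly causal for the outcome (log-OR 0.15
# and 0.12 per lipid SD), the rest are null. Each cohort is an
# independent outcome GWAS over the union of panels. A separate
# cholesterol -> sterol-ester -> CRC triplet provides the mediation
# inputs (a = 0.5, b = 0.16, total effect 0.1, so the true mediated
# proportion is 80%).
#
# Outputs (TSV, results/data/): lipid_<name>.tsv, cohort_<id>.tsv,
# tc.tsv, sterol_ester.tsv, crc_mediation.tsv, truth tables.

library(lipidmr)

seed <- 20260401L
out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

n_lipids <- 10
theta <- c(0.15, 0.12, rep(0, n_lipids - 2))
cohorts <- paste0("cohort", 1:4)

lipid_sims <- lapply(seq_len(n_lipids), function(j) {
  sim <- simulate_triplet(sim_config(
    n_snps = 40, n_snps_mediator = 0, n_outcome = 20000,
    theta_total = theta[j], seed = seed + j))
  # per-lipid SNP namespace so cohort GWAS can be stacked across panels
  rename <- function(st) { st$snp <- sprintf("L%02d_%s", j, st$snp); st }
  sim$exposure <- rename(sim$exposure)
  sim$outcome <- rename(sim$outcome)
  sim$truth$snp <- sprintf("L%02d_%s", j, sim$truth$snp)
  sim
})
names(lipid_sims) <- sprintf("lipid_%02d", seq_len(n_lipids))

# disease-specific susceptibility loci: strong in every CRC cohort, null
# for every lipid (there is no CRC -> lipid arrow in the truth), so the
# reverse-MR stage has genome-wide-significant instruments to select
set.seed(seed + 500L)
n_disease <- 30
disease <- data.frame(
  snp = sprintf("D_rs%03d", seq_len(n_disease)),
  chr = as.character(sample(1:22, n_disease, replace = TRUE)),
  pos = sample.int(2.4e8, n_disease),
  ea = sample(c("A", "C", "G", "T"), n_disease, replace = TRUE),
  stringsAsFactors = FALSE)
disease$oa <- vapply(disease$ea,
                     function(a) sample(setdiff(c("A", "C", "G", "T"), a), 1), "")
disease$eaf <- runif(n_disease, 0.05, 0.5)
disease$gamma <- abs(rnorm(n_disease, 0, 0.2))  # per-allele log-OR on CRC

gwas_rows <- function(true_beta, n, seed_i) {
  se <- 1 / sqrt(2 * disease$eaf * (1 - disease$eaf) * n)
  set.seed(seed_i)
  beta <- true_beta + rnorm(n_disease, 0, se)
  data.frame(snp = disease$snp, chr = disease$chr, pos = disease$pos,
             ea = disease$ea, oa = disease$oa, eaf = disease$eaf,
             beta = beta, se = se,
             pval = pmax(2 * pnorm(-abs(beta / se)), 1e-300), n = n,
             stringsAsFactors = FALSE)
}

# lipid GWAS gain null rows at the disease loci
for (j in seq_along(lipid_sims)) {
  ex <- rbind(as.data.frame(lipid_sims[[j]]$exposure),
              gwas_rows(0, 1e5, seed + 600L + j))
  lipid_sims[[j]]$exposure <- summary_stats(ex, names(lipid_sims)[j])
}

# each cohort: independent noise draw around the same true outcome effects,
# plus its own draw at the disease loci
for (ci in seq_along(cohorts)) {
  rows <- lapply(seq_along(lipid_sims), function(j) {
    sim <- lipid_sims[[j]]
    d <- as.data.frame(sim$outcome)
    set.seed(seed + 1000L * ci + j)
    d$beta <- sim$truth$beta_out_true + rnorm(nrow(d), 0, d$se)
    d$pval <- pmax(2 * pnorm(-abs(d$beta / d$se)), 1e-300)
    d
  })
  rows$disease <- gwas_rows(disease$gamma, 20000, seed + 700L + ci)
  cohort <- summary_stats(do.call(rbind, rows), cohorts[ci], "binary")
  write_summary_stats(cohort, file.path(out_dir, paste0(cohorts[ci], ".tsv")))
}

for (nm in names(lipid_sims))
  write_summary_stats(lipid_sims[[nm]]$exposure,
                      file.path(out_dir, paste0(nm, ".tsv")))

# mediation triplet: total cholesterol -> sterol ester -> CRC
med_sim <- simulate_triplet(sim_config(
  n_snps = 50, n_snps_mediator = 50, n_outcome = 20000,
  a_true = 0.5, b_true = 0.16, theta_total = 0.1, seed = seed + 99L))
write_summary_stats(med_sim$exposure, file.path(out_dir, "tc.tsv"))
write_summary_stats(med_sim$mediator, file.path(out_dir, "sterol_ester.tsv"))
write_summary_stats(med_sim$outcome, file.path(out_dir, "crc_mediation.tsv"))

truth <- do.call(rbind, lapply(seq_along(lipid_sims), function(j)
  cbind(lipid = names(lipid_sims)[j], theta_true = theta[j],
        lipid_sims[[j]]$truth)))
write.table(truth, file.path(out_dir, "truth_lipids.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(med_sim$truth, file.path(out_dir, "truth_mediation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "wrote %d lipid GWAS (2 causal: log-OR %.2f, %.2f), %d cohort GWAS of %d SNPs,\nand a mediation triplet (true mediated proportion %.0f%%) to %s\n",
  n_lipids, theta[1], theta[2], length(cohorts), 40 * n_lipids,
  100 * 0.5 * 0.16 / 0.1, out_dir))
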
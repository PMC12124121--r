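test_that("summary_stats validates columns and rejects malformed rows", {
  d <- toy_stats_df(3)
  expect_error(summary_stats(d[setdiff(names(d), "se")], "t"), "mandatory column")
  d$se[2] <- 0
  expect_warning(st <- summary_stats(d, "t"), "1 malformed row")
  expect_equal(nrow(st), 2)
  d2 <- toy_stats_df(3)
  d2$snp[2] <- d2$snp[1]
  expect_error(summary_stats(d2, "t"), "duplicated")
})

test_that("TSV round trip preserves records and attributes", {
  sim <- simulate_triplet(sim_config(n_snps = 25, theta_total = 0.1, seed = 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(sim$exposure, path)
  back <- read_summary_stats(path, trait_id = "exposure")
  expect_equal(as.data.frame(back), as.data.frame(sim$exposure), tolerance = 1e-12)
  expect_equal(attr(back, "trait_id"), "exposure")

  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_summary_stats(sim$exposure, gz)
  expect_equal(as.data.frame(read_summary_stats(gz, trait_id = "exposure")),
               as.data.frame(sim$exposure), tolerance = 1e-12)
})

test_that("column maps translate foreign headers", {
  d <- toy_stats_df(4)
  names(d)[names(d) == "snp"] <- "SNP"
  names(d)[names(d) == "pval"] <- "p"
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  st <- read_summary_stats(path, trait_id = "t", column_map = c(snp = "SNP", pval = "p"))
  expect_equal(nrow(st), 4)
  expect_error(read_summary_stats(path, column_map = c(snp = "rsid")), "absent")
})

test_that("harmonize keeps matching coding untouched and resolves swaps and strand flips", {
  exp <- toy_stats(6, trait_id = "exp")
  out_df <- as.data.frame(exp)
  out_df$beta <- 0.2
  out <- summary_stats(out_df, "out", "binary")
  h <- harmonize(exp, out)
  expect_true(all(h$action == "none"))
  expect_equal(h$beta_out, rep(0.2, 6))

  # swap alleles on one record
  out_df2 <- out_df
  out_df2[1, c("ea", "oa")] <- out_df2[1, c("oa", "ea")]
  out_df2$eaf[1] <- 1 - out_df2$eaf[1]
  h2 <- harmonize(exp, summary_stats(out_df2, "out", "binary"))
  expect_equal(h2$action[h2$snp == out_df2$snp[1]], "swapped")
  expect_equal(h2$beta_out[h2$snp == out_df2$snp[1]], -0.2)

  # strand-complement a non-palindromic record: no sign change
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  out_df3 <- out_df
  out_df3$ea[2] <- comp[[out_df$ea[2]]]
  out_df3$oa[2] <- comp[[out_df$oa[2]]]
  h3 <- harmonize(exp, summary_stats(out_df3, "out", "binary"))
  expect_equal(h3$action[h3$snp == out_df3$snp[2]], "flipped")
  expect_equal(h3$beta_out[h3$snp == out_df3$snp[2]], 0.2)
})

test_that("palindromic SNPs are frequency-oriented when the MAF allows and dropped otherwise", {
  base <- toy_stats_df(3)
  base$ea <- "A"; base$oa <- "T"
  base$eaf <- c(0.2, 0.2, 0.48)
  exp <- summary_stats(base, "exp")
  out_df <- base
  out_df$beta <- 0.1
  out_df$eaf <- c(0.2, 0.8, 0.49)  # aligned, anti-aligned, uncallable
  h <- harmonize(exp, summary_stats(out_df, "out", "binary"))
  log <- attr(h, "action_log")
  expect_equal(log$action[log$snp == base$snp[1]], "none")
  expect_equal(log$action[log$snp == base$snp[2]], "swapped")
  expect_equal(log$action[log$snp == base$snp[3]], "dropped_palindromic")
  expect_equal(nrow(h), 2)
  expect_equal(h$beta_out[h$snp == base$snp[2]], -0.1)
})

test_that("harmonize is idempotent and its action log partitions the intersection", {
  sim <- simulate_triplet(sim_config(n_snps = 80, theta_total = 0.2, seed = 13))
  noisy <- inject_harmonization_noise(sim$outcome, flip_fraction = 0.4, seed = 2)
  h <- harmonize(sim$exposure, noisy)
  log <- attr(h, "action_log")
  expect_equal(nrow(log), length(intersect(sim$exposure$snp, noisy$snp)))
  expect_equal(sum(log$action %in% c("none", "flipped", "swapped")), nrow(h))

  redone <- harmonize(sim$exposure[sim$exposure$snp %in% h$snp, ],
                      stats_from_harmonized(h))
  expect_true(all(redone$action == "none"))
  expect_equal(redone$beta_out, h$beta_out)
})

test_that("empty intersections and empty inputs are fatal with a clear message", {
  a <- toy_stats(3, trait_id = "a")
  b_df <- toy_stats_df(3)
  b_df$snp <- paste0("other", 1:3)
  b <- summary_stats(b_df, "b")
  expect_error(harmonize(a, b), "no shared SNPs")
  expect_error(harmonize(a[0, ], b), "empty")
})
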
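test_that("p-value thresholding is strict and matches a direct scan", {
  d <- toy_stats_df(3)
  d$pval <- c(1e-7, 1e-5, 0.2)
  st <- summary_stats(d, "t")
  expect_equal(nrow(threshold_instruments(st, 5e-6)), 1)
  expect_equal(threshold_instruments(st, 5e-6)$snp, d$snp[1])
  expect_equal(nrow(threshold_instruments(st, 1.0)), 3)
  sim <- simulate_triplet(sim_config(n_snps = 200, null_fraction = 0.5, seed = 8))
  kept <- threshold_instruments(sim$exposure, 5e-6)
  expect_equal(kept$snp, sim$exposure$snp[sim$exposure$pval < 5e-6])
})

test_that("clumping keeps only the best SNP in a fully linked block and is the identity without LD", {
  d <- toy_stats_df(5)
  d$chr <- "1"; d$pos <- 1000
  d$pval <- c(0.3, 1e-8, 0.05, 1e-4, 0.2)
  st <- summary_stats(d, "t")
  full_ld <- ld_matrix(matrix(1, 5, 5), d$snp)
  expect_equal(clump(st, full_ld)$snp, d$snp[2])
  ident_ld <- ld_matrix(diag(5), d$snp)
  expect_equal(clump(st, ident_ld)$snp, d$snp)
  expect_equal(clump(st, NULL)$snp, d$snp)  # unlinked when no panel given
})

test_that("clumping ties on p break lexicographically by snp id", {
  d <- toy_stats_df(2)
  d$chr <- "1"; d$pos <- c(100, 200); d$pval <- c(0.01, 0.01)
  d$snp <- c("rsB", "rsA")
  st <- summary_stats(d, "t")
  ld <- ld_matrix(matrix(c(1, 1, 1, 1), 2), d$snp)
  expect_equal(clump(st, ld)$snp, "rsA")
})

test_that("clumping agrees with the pairwise verification oracle on random LD", {
  set.seed(99)
  k <- 20
  d <- toy_stats_df(k, seed = 99)
  d$chr <- as.character(sample(1:2, k, TRUE))
  d$pos <- sample.int(2e7, k)
  d$pval <- runif(k)
  st <- summary_stats(d, "t")
  A <- matrix(runif(k * k), k)
  r2 <- (A + t(A)) / 2 * 0.003   # values straddling the 0.001 threshold
  diag(r2) <- 1
  ld <- ld_matrix(r2, d$snp)
  kept <- clump(st, ld, r2_threshold = 0.001, window_kb = 10000)$snp

  conflicts <- function(a, b) {
    ia <- match(a, d$snp); ib <- match(b, d$snp)
    d$chr[ia] == d$chr[ib] & abs(d$pos[ia] - d$pos[ib]) <= 1e7 &
      ld[a, b] >= 0.001
  }
  # no retained pair conflicts
  for (a in kept) for (b in setdiff(kept, a))
    expect_false(conflicts(a, b))
  # every removed SNP conflicts with a better-ranked retained SNP
  rank_key <- order(d$pval, d$snp)
  pos_of <- match(d$snp, d$snp[rank_key])
  for (r in setdiff(d$snp, kept)) {
    better <- kept[pos_of[match(kept, d$snp)] < pos_of[match(r, d$snp)]]
    expect_true(any(vapply(better, conflicts, TRUE, a = r)))
  }
})

test_that("outcome-associated SNPs are removed by the recomputed two-sided p", {
  h <- harmonized_from_vectors(c(0.1, 0.1, 0.1), rep(0.01, 3),
                               c(0.25, 0, 0.05), rep(0.05, 3))
  kept <- filter_outcome_associated(h, 5e-5)
  expect_equal(kept$snp, h$snp[2:3])          # z = 5 removed, z = 0 and 1 kept
  expect_equal(attr(kept, "dropped_outcome"), h$snp[1])
  sim <- simulate_triplet(sim_config(n_snps = 150, theta_total = 0.3, seed = 17))
  hs <- harmonize(sim$exposure, sim$outcome)
  brute <- hs$snp[2 * pnorm(-abs(hs$beta_out / hs$se_out)) < 5e-5]
  expect_equal(attr(filter_outcome_associated(hs, 5e-5), "dropped_outcome"), brute)
})

test_that("Steiger filtering drops only stronger-outcome SNPs, strictly", {
  h <- harmonized_from_vectors(c(1, 0.5, 0.1), c(0.1, 0.1, 0.1),
                               c(0.1, 0.5, 0.9), c(0.1, 0.1, 0.1))
  out <- steiger_filter(h)
  expect_equal(out$snp, h$snp[1:2])           # equal t retained, weaker exp dropped
  expect_equal(attr(out, "dropped_steiger"), h$snp[3])
  expect_error(steiger_filter(h, n_exp = 2, n_out = 2), "sample sizes")
})

test_that("under true forward causation with strong instruments Steiger drops almost nothing", {
  dropped <- vapply(1:20, function(s) {
    sim <- simulate_triplet(sim_config(n_snps = 50, theta_total = 0.2, seed = 100 + s))
    h <- harmonize(sim$exposure, sim$outcome)
    length(attr(steiger_filter(h), "dropped_steiger")) / nrow(h)
  }, numeric(1))
  expect_lt(mean(dropped), 0.05)
})

test_that("the F statistic is the squared exposure z score", {
  h <- harmonized_from_vectors(c(0.1, 0), c(0.05, 0.05), c(0, 0), c(1, 1))
  expect_equal(unname(f_statistic(h)), c(4, 0))
  sim <- simulate_triplet(sim_config(n_snps = 30, seed = 23))
  hs <- harmonize(sim$exposure, sim$outcome)
  expect_equal(unname(f_statistic(hs)), (hs$beta_exp / hs$se_exp)^2)
})

test_that("select_instruments provenance partitions every candidate SNP", {
  sim <- simulate_triplet(sim_config(n_snps = 60, theta_total = 0.25,
                                     null_fraction = 0.3, seed = 41))
  sel <- select_instruments(sim$exposure, sim$outcome, seed = 7,
                            presso_n_sim = 300)
  prov <- attr(sel, "provenance")
  expect_equal(nrow(prov), 60)
  expect_setequal(prov$snp[prov$retained], sel$snp)
  # each candidate is accounted for by exactly one fate
  not_selected <- !prov$passed_p | !prov$clump_index
  dropped_h <- !not_selected & !is.na(prov$action) &
    !prov$action %in% c("none", "flipped", "swapped")
  filtered <- prov$outcome_filtered | prov$steiger_dropped | prov$presso_dropped
  expect_equal(not_selected | dropped_h | filtered | prov$retained,
               rep(TRUE, 60))
  expect_equal(sum(prov$retained) +
                 sum(not_selected | dropped_h | filtered), 60)
  expect_true(all(is.finite(prov$f_stat[prov$retained])))
})

test_that("filters are invariant to input row order", {
  sim <- simulate_triplet(sim_config(n_snps = 40, theta_total = 0.2, seed = 53))
  shuffle <- sample(40)
  a <- select_instruments(sim$exposure, sim$outcome, seed = 3, presso_n_sim = 200)
  b <- select_instruments(sim$exposure[shuffle, ], sim$outcome, seed = 3,
                          presso_n_sim = 200)
  expect_setequal(a$snp, b$snp)
})

test_that("LD matrices survive a TSV round trip and are validated", {
  r2 <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  ld <- ld_matrix(r2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(ld, path)
  expect_equal(unclass(read_ld_matrix(path)), unclass(ld))
  expect_error(ld_matrix(matrix(c(1, 0.2, 0.4, 1), 2, dimnames = list(1:2, 1:2))),
               "symmetric")
  expect_error(ld_matrix(matrix(c(1, 2, 2, 1), 2, dimnames = list(1:2, 1:2))),
               "0, 1")
})
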
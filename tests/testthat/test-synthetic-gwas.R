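test_that("simulate_triplet is reproducible under a seed and varies across seeds", {
  cf <- sim_config(n_snps = 50, theta_total = 0.1, seed = 1)
  s1 <- simulate_triplet(cf)
  s2 <- simulate_triplet(cf)
  expect_identical(s1, s2)
  s3 <- simulate_triplet(sim_config(n_snps = 50, theta_total = 0.1, seed = 2))
  expect_false(identical(s1$exposure$beta, s3$exposure$beta))
})

test_that("config validation rejects out-of-range fields", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(effect_sd = 0), "effect_sd")
  expect_error(sim_config(null_fraction = 1.2), "null_fraction")
  expect_error(sim_config(n_outcome = 1), "n_outcome")
  expect_error(sim_config(theta_total = NA), "theta_total")
})

test_that("reported SEs follow the allele-frequency sample-size formula and calibrate the noise", {
  cf <- sim_config(n_snps = 2000, theta_total = 0.1, a_true = 0.3, seed = 11)
  sim <- simulate_triplet(cf)
  maf <- sim$exposure$eaf
  expect_equal(sim$exposure$se, 1 / sqrt(2 * maf * (1 - maf) * cf$n_exposure))
  expect_equal(sim$outcome$se, 1 / sqrt(2 * maf * (1 - maf) * cf$n_outcome))
  for (trait in c("exposure", "mediator", "outcome")) {
    z <- (sim[[trait]]$beta - sim$truth[[paste0("beta_", substr(trait, 1, 3), "_true")]]) /
      sim[[trait]]$se
    expect_lt(abs(mean(z)), 3 / sqrt(cf$n_snps))   # mean error ~ 0
    expect_lt(abs(sd(z) - 1), 0.1)                 # noise SD matches reported SE
  }
})

test_that("the noise-free limit recovers the causal structure exactly per SNP", {
  cf <- sim_config(n_snps = 40, n_exposure = 1e16, n_mediator = 1e16,
                   n_outcome = 1e16, a_true = 0.5, b_true = 0.4,
                   theta_total = 0.2, seed = 3)
  sim <- simulate_triplet(cf)
  expect_close(sim$outcome$beta / sim$exposure$beta, 0.2, 1e-3)
  expect_close(sim$mediator$beta / sim$exposure$beta, 0.5, 1e-3)
  expect_close(sim$truth$wald_true, 0.2, 1e-12)
})

test_that("null fraction zeroes exposure effects and flags them", {
  cf <- sim_config(n_snps = 40, null_fraction = 0.25, seed = 5)
  sim <- simulate_triplet(cf)
  expect_equal(sum(sim$truth$is_null), 10)
  expect_true(all(sim$truth$beta_exp_true[sim$truth$is_null] == 0))
  expect_true(all(sim$truth$beta_exp_true[!sim$truth$is_null] != 0))
})

test_that("mediator-specific SNPs act on mediator and outcome only through b", {
  cf <- sim_config(n_snps = 10, n_snps_mediator = 15, a_true = 0.5,
                   b_true = 0.4, theta_total = 0.25, seed = 9)
  sim <- simulate_triplet(cf)
  tr <- sim$truth
  med <- tr$role == "mediator_iv"
  expect_equal(sum(med), 15)
  expect_true(all(tr$beta_exp_true[med] == 0))
  expect_equal(tr$beta_out_true[med], 0.4 * tr$beta_med_true[med])
  expect_equal(tr$beta_med_true[!med], 0.5 * tr$beta_exp_true[!med])
})

test_that("harmonization noise with zero fractions is the identity", {
  st <- toy_stats(10)
  out <- inject_harmonization_noise(st, 0, 0, seed = 1)
  expect_equal(as.data.frame(out), as.data.frame(st), ignore_attr = TRUE)
  expect_true(all(attr(out, "injected")$action == "none"))
})

test_that("an allele swap negates beta and complements eaf, and is undone by harmonize", {
  sim <- simulate_triplet(sim_config(n_snps = 100, theta_total = 0.2, seed = 21))
  noisy <- inject_harmonization_noise(sim$outcome, flip_fraction = 0.5, seed = 77)
  inj <- attr(noisy, "injected")
  expect_equal(sum(inj$action != "none"), 50)
  swapped <- inj$action == "swap"
  expect_equal(noisy$beta[swapped], -sim$outcome$beta[swapped])
  expect_equal(noisy$eaf[swapped], 1 - sim$outcome$eaf[swapped])
  strand <- inj$action == "strand"
  expect_equal(noisy$beta[strand], sim$outcome$beta[strand])

  h_clean <- harmonize(sim$exposure, sim$outcome)
  h_noisy <- harmonize(sim$exposure, noisy)
  shared <- intersect(h_clean$snp, h_noisy$snp)
  expect_equal(h_noisy$beta_out[match(shared, h_noisy$snp)],
               h_clean$beta_out[match(shared, h_clean$snp)])
  # repeat call with the same seed alters the identical subset
  noisy2 <- inject_harmonization_noise(sim$outcome, flip_fraction = 0.5, seed = 77)
  expect_identical(as.data.frame(noisy), as.data.frame(noisy2))
})

test_that("palindrome injection with a shared seed creates consistent A/T-C/G pairs", {
  sim <- simulate_triplet(sim_config(n_snps = 60, theta_total = 0.2, seed = 31))
  exp_p <- inject_harmonization_noise(sim$exposure, palindrome_fraction = 0.3, seed = 5)
  out_p <- inject_harmonization_noise(sim$outcome, palindrome_fraction = 0.3, seed = 5)
  pal_e <- attr(exp_p, "injected")$action == "palindrome"
  pal_o <- attr(out_p, "injected")$action == "palindrome"
  expect_equal(pal_e, pal_o)
  expect_equal(sum(pal_e), 18)
  expect_true(all(exp_p$oa[pal_e] == c(A = "T", T = "A", C = "G", G = "C")[exp_p$ea[pal_e]]))
})
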
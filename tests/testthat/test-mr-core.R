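test_that("the Wald ratio is outcome over exposure beta with first-order SE", {
  est <- wald_ratio(0.5, 0.01, 0.1, 0.05)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)
  expect_equal(wald_ratio(0.5, 0.01, 0, 0.05)$beta, 0)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.05), "beta_exp = 0")
  so <- wald_ratio(0.5, 0.1, 0.1, 0.05, second_order = TRUE)
  expect_equal(so$se, sqrt(0.05^2 / 0.25 + 0.01 * 0.01 / 0.0625))
})

test_that("IVW equals the mean of ratios under equal weights and the Wald ratio when duplicated", {
  h <- harmonized_from_vectors(c(1, 1), c(0.01, 0.01), c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(mr_ivw(h, "fe")$beta, 0.2)
  single <- wald_ratio(0.4, 0.01, 0.1, 0.05)
  dup <- harmonized_from_vectors(rep(0.4, 4), rep(0.01, 4), rep(0.1, 4), rep(0.05, 4))
  fit <- mr_ivw(dup, "fe")
  expect_equal(fit$beta, single$beta)
  expect_equal(fit$se, single$se / sqrt(4))
  expect_error(mr_ivw(h[1, ], "fe"), "wald_ratio")
})

test_that("closed-form IVW matches an independent WLS-through-origin solver to 1e-10", {
  set.seed(7)
  for (i in 1:25) {
    k <- sample(3:40, 1)
    h <- harmonized_from_vectors(rnorm(k, 0.2, 0.1), runif(k, 0.005, 0.02),
                                 rnorm(k, 0, 0.1), runif(k, 0.02, 0.2))
    fit <- mr_ivw(h, "fe")
    oracle <- lm(beta_out ~ 0 + beta_exp, data = h, weights = 1 / h$se_out^2)
    expect_lt(abs(fit$beta - unname(coef(oracle))), 1e-10)
    se_unscaled <- summary(oracle)$coefficients[1, 2] / summary(oracle)$sigma
    expect_lt(abs(fit$se - se_unscaled), 1e-10)
    mre <- mr_ivw(h, "mre")
    expect_gte(mre$se, fit$se)
    expect_equal(mre$se == fit$se, fit$extra$Q <= k - 1)
  }
})

test_that("MR-Egger recovers an exact affine relation and its diagnostics", {
  bx <- c(0.1, 0.15, 0.2, 0.3, 0.42)
  h <- harmonized_from_vectors(bx, rep(0.01, 5), 0.1 + 0.3 * bx, rep(0.05, 5))
  fit <- mr_egger(h)
  expect_equal(fit$beta, 0.3, tolerance = 1e-10)
  expect_equal(fit$extra$intercept, 0.1, tolerance = 1e-10)
  expect_equal(fit$extra$Q, 0, tolerance = 1e-18)
  expect_error(mr_egger(h[1:2, ]), "3 SNPs")
  # orientation: flipping the sign of an exposure beta leaves the fit unchanged
  h2 <- h
  h2$beta_exp[1] <- -h2$beta_exp[1]
  h2$beta_out[1] <- -h2$beta_out[1]
  fit2 <- mr_egger(h2)
  expect_equal(fit2$beta, fit$beta)
  expect_equal(fit2$extra$intercept, fit$extra$intercept)
})

test_that("MR-Egger slope and intercept match a weighted lm oracle", {
  set.seed(11)
  k <- 20
  bx <- abs(rnorm(k, 0.2, 0.1)) + 0.01
  h <- harmonized_from_vectors(bx, rep(0.01, k),
                               0.02 + 0.25 * bx + rnorm(k, 0, 0.05),
                               runif(k, 0.03, 0.1))
  fit <- mr_egger(h)
  w <- 1 / h$se_out^2
  oracle <- lm(beta_out ~ beta_exp, data = h, weights = w)
  expect_equal(fit$beta, unname(coef(oracle)[2]), tolerance = 1e-10)
  expect_equal(fit$extra$intercept, unname(coef(oracle)[1]), tolerance = 1e-10)
  # the MRE inflation floors the lm SE at its unscaled (sigma = 1) value
  se_lm <- summary(oracle)$coefficients[2, 2]
  expect_equal(fit$se, max(se_lm, se_lm / summary(oracle)$sigma), tolerance = 1e-10)
})

test_that("the weighted median interpolates the 50% weight point", {
  h <- harmonized_from_vectors(c(1, 1, 1), c(0.01, 0.01, 0.01),
                               c(0.1, 0.2, 0.9), c(0.1, 0.1, 0.1))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 0.2)
  # a SNP holding the majority of the weight dictates the estimate
  hd <- harmonized_from_vectors(c(1, 1, 1), c(0.01, 0.01, 0.01),
                                c(0.5, 0.2, 0.9), c(0.05, 0.2, 0.2))
  expect_equal(mr_weighted_median(hd, n_boot = 50, seed = 1)$beta, 0.5)
  # bootstrap SE is reproducible under a seed
  a <- mr_weighted_median(h, n_boot = 200, seed = 9)
  b <- mr_weighted_median(h, n_boot = 200, seed = 9)
  expect_identical(a$se, b$se)
})

test_that("the weighted median resists a large invalid minority where IVW does not", {
  set.seed(31)
  k <- 40
  bx <- abs(rnorm(k, 0.3, 0.05))
  by <- 0.2 * bx + rnorm(k, 0, 0.01)
  by[1:18] <- by[1:18] + 0.15   # 45% of instruments pleiotropic
  h <- harmonized_from_vectors(bx, rep(0.01, k), by, rep(0.01, k))
  med <- mr_weighted_median(h, n_boot = 100, seed = 2)
  ivw <- mr_ivw(h, "fe")
  expect_lt(abs(med$beta - 0.2), 0.08)
  expect_gt(ivw$beta - 0.2, 0.15)
})

test_that("the weighted mode finds the dominant ratio cluster", {
  h0 <- harmonized_from_vectors(rep(1, 4), rep(0.01, 4), rep(0.3, 4), rep(0.1, 4))
  expect_equal(mr_weighted_mode(h0, n_boot = 20, seed = 1)$beta, 0.3)
  set.seed(5)
  k <- 30
  bx <- abs(rnorm(k, 0.3, 0.05))
  ratio <- c(rep(0.2, 20), rep(1.0, 10)) + rnorm(k, 0, 0.02)
  h <- harmonized_from_vectors(bx, rep(0.01, k), ratio * bx, rep(0.01, k))
  m1 <- mr_weighted_mode(h, n_boot = 50, seed = 3)
  expect_lt(abs(m1$beta - 0.2), 0.05)
  m2 <- mr_weighted_mode(h, phi = 2, n_boot = 50, seed = 3)
  expect_true(is.finite(m2$beta))  # smoother bandwidth still returns an estimate
})

test_that("Cochran's Q matches hand arithmetic and is zero for identical ratios", {
  h_eq <- harmonized_from_vectors(c(1, 1, 1), rep(0.01, 3), rep(0.25, 3), rep(0.1, 3))
  q0 <- cochran_q(h_eq, 0.25)
  expect_equal(q0$Q, 0)
  expect_equal(q0$pval, 1)
  # two SNPs, unit ratio weights, ratios 0 and 1 about 0.5
  h2 <- harmonized_from_vectors(c(1, 1), c(0.01, 0.01), c(0, 1), c(1, 1))
  expect_equal(cochran_q(h2, 0.5)$Q, 0.5)
  expect_equal(cochran_q(h2, 0.5)$df, 1)
})

test_that("leave-one-out returns one IVW row per SNP and isolates a spiked outlier", {
  h <- harmonized_from_vectors(c(0.2, 0.3, 0.25), rep(0.01, 3),
                               c(0.04, 0.06, 0.05), rep(0.05, 3))
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 3)
  expect_equal(loo$snp, h$snp)

  set.seed(19)
  k <- 20
  bx <- abs(rnorm(k, 0.3, 0.05))
  by <- 0.2 * bx + rnorm(k, 0, 0.02)
  by[7] <- by[7] + 0.5
  hs <- harmonized_from_vectors(bx, rep(0.01, k), by, rep(0.02, k))
  loo2 <- leave_one_out(hs)
  full_beta <- attr(loo2, "full")$beta
  expect_equal(which.max(abs(loo2$beta - full_beta)), 7)
})

test_that("the primary-estimate rule follows pleiotropy, then heterogeneity", {
  mk_q <- function(p) structure(list(Q = 1, df = 9, pval = p), class = "q_test")
  fe <- lipidmr:::mr_estimate("ivw_fe", 0.2, 0.05, 10)
  mre <- lipidmr:::mr_estimate("ivw_mre", 0.2, 0.08, 10)
  egger <- lipidmr:::mr_estimate("egger", 0.15, 0.1, 10,
                                 extra = list(intercept = 0.05, intercept_se = 0.01,
                                              intercept_p = 0.01))
  expect_equal(select_primary(fe, mre, egger, mk_q(0.8),
                              intercept_p = 0.9)$method, "ivw_fe")
  expect_equal(select_primary(fe, mre, egger, mk_q(0.01),
                              intercept_p = 0.5)$method, "ivw_mre")
  expect_equal(select_primary(fe, mre, egger, mk_q(0.01))$method, "egger")
  # a significant but negligible intercept (< 0.01) does not trigger Egger
  tiny <- lipidmr:::mr_estimate("egger", 0.15, 0.1, 10,
                                extra = list(intercept = 0.005, intercept_se = 0.001,
                                             intercept_p = 0.001))
  expect_equal(select_primary(fe, mre, tiny, mk_q(0.5))$method, "ivw_fe")
})

test_that("mr_suite degrades gracefully with few instruments", {
  h1 <- harmonized_from_vectors(0.4, 0.01, 0.1, 0.05)
  s1 <- mr_suite(h1)
  expect_equal(s1$status, "single_snp")
  expect_equal(s1$primary$beta, 0.25)
  h0 <- h1[0, ]
  expect_equal(mr_suite(h0)$status, "insufficient_instruments")
  h2 <- harmonized_from_vectors(c(0.4, 0.3), c(0.01, 0.01), c(0.1, 0.08),
                                c(0.05, 0.05))
  s2 <- mr_suite(h2)
  expect_equal(s2$status, "ok")
  expect_null(s2$estimates$egger)
})
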
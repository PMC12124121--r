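#' Configuration for the synthetic GWAS generator
#'
#' Describes the generative model behind [simulate_triplet()]: a set of
#' independent biallelic SNPs instrumenting a continuous exposure (e.g.
#' circulating total cholesterol in SD units), a continuous mediator
#' (a lipid species), and a binary outcome (colorectal cancer, log-odds
#' scale), wired as exposure -> mediator -> outcome with an additional
#' direct exposure -> outcome path. The total causal effect of the
#' exposure on the outcome is `theta_total`; of that, `a_true * b_true`
#' flows through the mediator and `theta_total - a_true * b_true` is
#' direct.
#'
#' @param n_snps number of candidate instruments for the exposure.
#' @param n_snps_mediator number of additional SNPs acting on the mediator
#'   directly (the mediator's own instruments, needed to estimate the
#'   mediator -> outcome path free of the exposure's direct effect).
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes of the three
#'   (non-overlapping) study samples.
#' @param maf_range minor/effect allele frequency bounds, within (0, 0.5].
#' @param effect_sd SD of true per-SNP exposure (and mediator-specific)
#'   effects, in trait SD units per allele. The default 0.2 reflects the
#'   large-effect loci that instrument molecular lipid traits; it keeps
#'   instruments strong (mean F in the hundreds at the default sample
#'   sizes) so first-order MR estimators are essentially unattenuated.
#' @param effect_sign `"positive"` draws true instrument effects from a
#'   half-normal so all instruments raise their trait (the orientation a
#'   directional-pleiotropy analysis presumes); `"symmetric"` draws them
#'   from a centred normal.
#' @param theta_total total causal effect of exposure on outcome
#'   (log-odds per exposure SD).
#' @param a_true exposure -> mediator effect (mediator SD per exposure SD).
#' @param b_true mediator -> outcome effect (log-odds per mediator SD).
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of horizontal
#'   pleiotropic effects added to outcome betas of exposure instruments
#'   (mean != 0 gives directional pleiotropy; both 0 disables it).
#' @param correlated_pleiotropy if `TRUE`, pleiotropic effects are made
#'   proportional to instrument strength (violating the InSIDE
#'   assumption); default `FALSE` keeps them independent.
#' @param null_fraction fraction of the `n_snps` exposure candidates with
#'   exactly zero exposure effect.
#' @param seed RNG seed making the draw reproducible.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_triplet()]
#' @export
sim_config <- function(n_snps = 50L,
                       n_snps_mediator = 0L,
                       n_exposure = 100000L,
                       n_mediator = 100000L,
                       n_outcome = 100000L,
                       maf_range = c(0.05, 0.5),
                       effect_sd = 0.2,
                       effect_sign = c("positive", "symmetric"),
                       theta_total = 0,
                       a_true = 0,
                       b_true = 0,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       correlated_pleiotropy = FALSE,
                       null_fraction = 0,
                       seed = NULL) {
  effect_sign <- match.arg(effect_sign)
  check_scalar(n_snps, "n_snps", lower = 1)
  check_scalar(n_snps_mediator, "n_snps_mediator", lower = 0)
  for (nm in c("n_exposure", "n_mediator", "n_outcome"))
    check_scalar(get(nm), nm, lower = 2)
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      any(!is.finite(maf_range)) || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("'maf_range' must be ordered bounds within (0, 0.5]", call. = FALSE)
  check_scalar(effect_sd, "effect_sd", lower = 0, strict_lower = TRUE)
  for (nm in c("theta_total", "a_true", "b_true", "pleiotropy_mean"))
    check_scalar(get(nm), nm)
  check_scalar(pleiotropy_sd, "pleiotropy_sd", lower = 0)
  check_scalar(null_fraction, "null_fraction", lower = 0, upper = 1)
  structure(list(
    n_snps = as.integer(n_snps), n_snps_mediator = as.integer(n_snps_mediator),
    # sample sizes stay double: noise-free limits use n beyond integer range
    n_exposure = as.numeric(n_exposure), n_mediator = as.numeric(n_mediator),
    n_outcome = as.numeric(n_outcome), maf_range = maf_range,
    effect_sd = effect_sd, effect_sign = effect_sign,
    theta_total = theta_total, a_true = a_true, b_true = b_true,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    correlated_pleiotropy = isTRUE(correlated_pleiotropy),
    null_fraction = null_fraction, seed = seed
  ), class = "sim_config")
}

#' Simulate an exposure/mediator/outcome GWAS summary-statistics triplet
#'
#' Draws per-SNP true effects under the mediation graph described in
#' [sim_config()] and returns, for each trait, summary statistics as an
#' independent GWAS sample would report them: the estimated beta is the
#' true beta plus Gaussian noise with standard deviation
#' `1 / sqrt(2 * maf * (1 - maf) * n_trait)` (the standard
#' standardized-trait approximation), the reported SE equals that noise
#' SD, and p-values are two-sided normal. The three traits' noise draws
#' are independent, mirroring a non-overlapping two-sample design.
#'
#' True effects: exposure instruments get `beta_exp ~ effect_sd`-scaled
#' draws (a `null_fraction` subset is exactly zero); the mediator
#' inherits `a_true * beta_exp` and mediator-specific SNPs add their own
#' draws; the outcome receives `theta_total * beta_exp` from exposure
#' instruments, `b_true * gamma` from mediator-specific SNPs, plus any
#' horizontal pleiotropy.
#'
#' @param config a [sim_config()] object.
#' @return A list with elements `exposure`, `mediator`, `outcome`
#'   (each a [summary_stats()] object over the same SNPs and alleles) and
#'   `truth`, a data frame holding per-SNP true effects, pleiotropic
#'   effects, role (`"exposure_iv"` or `"mediator_iv"`), null flags and
#'   the implied true Wald ratio.
#' @export
simulate_triplet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    m <- cf$n_snps + cf$n_snps_mediator
    role <- rep(c("exposure_iv", "mediator_iv"), c(cf$n_snps, cf$n_snps_mediator))
    snp <- sprintf("rs%06d", seq_len(m))
    chr <- as.character(sample(1:22, m, replace = TRUE))
    pos <- sample.int(2.4e8, m, replace = TRUE)
    maf <- stats::runif(m, cf$maf_range[1], cf$maf_range[2])
    ea <- sample(names(DNA_COMPLEMENT), m, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(names(DNA_COMPLEMENT), a), 1L), "")

    draw_effect <- function(k) {
      x <- stats::rnorm(k, 0, cf$effect_sd)
      if (cf$effect_sign == "positive") abs(x) else x
    }
    beta_exp_true <- numeric(m)
    beta_exp_true[role == "exposure_iv"] <- draw_effect(cf$n_snps)
    is_null <- rep(FALSE, m)
    n_null <- round(cf$null_fraction * cf$n_snps)
    if (n_null > 0) {
      idx <- sample(which(role == "exposure_iv"), n_null)
      beta_exp_true[idx] <- 0
      is_null[idx] <- TRUE
    }
    gamma_med <- numeric(m)
    if (cf$n_snps_mediator > 0)
      gamma_med[role == "mediator_iv"] <- draw_effect(cf$n_snps_mediator)

    pleio <- numeric(m)
    if (cf$pleiotropy_mean != 0 || cf$pleiotropy_sd > 0) {
      on_exp <- role == "exposure_iv"
      pleio[on_exp] <- stats::rnorm(sum(on_exp), cf$pleiotropy_mean, cf$pleiotropy_sd)
      if (cf$correlated_pleiotropy)
        pleio[on_exp] <- pleio[on_exp] *
          (beta_exp_true[on_exp] / max(cf$effect_sd, 1e-12))
    }

    beta_med_true <- cf$a_true * beta_exp_true + gamma_med
    beta_out_true <- cf$theta_total * beta_exp_true + cf$b_true * gamma_med + pleio

    make_stats <- function(true_beta, n, trait_id, trait_type) {
      se <- 1 / sqrt(2 * maf * (1 - maf) * n)
      beta <- true_beta + stats::rnorm(m, 0, se)
      summary_stats(data.frame(
        snp = snp, chr = chr, pos = pos, ea = ea, oa = oa, eaf = maf,
        beta = beta, se = se, pval = two_sided_p(beta / se), n = n,
        stringsAsFactors = FALSE
      ), trait_id = trait_id, trait_type = trait_type)
    }
    exposure <- make_stats(beta_exp_true, cf$n_exposure, "exposure", "continuous")
    mediator <- make_stats(beta_med_true, cf$n_mediator, "mediator", "continuous")
    outcome <- make_stats(beta_out_true, cf$n_outcome, "outcome", "binary")

    truth <- data.frame(
      snp = snp, role = role, is_null = is_null,
      beta_exp_true = beta_exp_true, beta_med_true = beta_med_true,
      beta_out_true = beta_out_true, pleiotropy = pleio,
      wald_true = ifelse(beta_exp_true != 0, beta_out_true / beta_exp_true, NA_real_),
      stringsAsFactors = FALSE
    )
    list(exposure = exposure, mediator = mediator, outcome = outcome, truth = truth)
  })
}

#' Perturb allele coding to stress-test harmonization
#'
#' Applies reversible allele-coding perturbations to a summary-statistics
#' table so that [harmonize()] against an unperturbed partner can be
#' checked for exact recovery. A fraction of records is altered by
#' swapping effect/other alleles (negating beta, complementing eaf),
#' reporting the complementary strand, or both; a further fraction has
#' its allele pair replaced by a palindromic one (A/T or C/G).
#'
#' The palindrome subset is drawn from a seed derived only from `seed`,
#' so calling this function on two tables generated over the same SNPs
#' with the same `seed` and `palindrome_fraction` makes the *same* SNPs
#' palindromic in both, as is true of a real shared variant.
#'
#' @param stats a [summary_stats()] object.
#' @param flip_fraction fraction of records receiving a swap/strand
#'   perturbation.
#' @param palindrome_fraction fraction of records converted to a
#'   palindromic allele pair.
#' @param seed RNG seed.
#' @return The perturbed `summary_stats`, with an attribute `injected`
#'   (data frame `snp`, `action` in `none | swap | strand | both |
#'   palindrome`) recording what was done.
#' @export
inject_harmonization_noise <- function(stats, flip_fraction = 0,
                                       palindrome_fraction = 0, seed = NULL) {
  stopifnot(inherits(stats, "summary_stats"))
  check_scalar(flip_fraction, "flip_fraction", lower = 0, upper = 1)
  check_scalar(palindrome_fraction, "palindrome_fraction", lower = 0, upper = 1)
  d <- as.data.frame(stats)
  m <- nrow(d)
  action <- rep("none", m)

  n_pal <- round(palindrome_fraction * m)
  if (n_pal > 0) {
    pal_idx <- with_seed(seed, sort(sample.int(m, n_pal)))
    # same-seed determinism keys palindrome identity to the SNP set alone
    d$oa[pal_idx] <- unname(DNA_COMPLEMENT[d$ea[pal_idx]])
    action[pal_idx] <- "palindrome"
  }
  n_flip <- round(flip_fraction * m)
  if (n_flip > 0) {
    perturb <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
      idx <- sort(sample.int(m, n_flip))
      list(idx = idx, kind = sample(c("swap", "strand", "both"), n_flip, replace = TRUE))
    })
    for (k in seq_along(perturb$idx)) {
      i <- perturb$idx[k]
      kind <- perturb$kind[k]
      if (kind %in% c("swap", "both")) {
        tmp <- d$ea[i]; d$ea[i] <- d$oa[i]; d$oa[i] <- tmp
        d$beta[i] <- -d$beta[i]
        d$eaf[i] <- 1 - d$eaf[i]
      }
      if (kind %in% c("strand", "both")) {
        d$ea[i] <- unname(DNA_COMPLEMENT[d$ea[i]])
        d$oa[i] <- unname(DNA_COMPLEMENT[d$oa[i]])
      }
      action[i] <- if (action[i] == "palindrome") "palindrome" else kind
    }
  }
  out <- summary_stats(d, trait_id = attr(stats, "trait_id"),
                       trait_type = attr(stats, "trait_type"))
  attr(out, "injected") <- data.frame(snp = d$snp, action = action,
                                      stringsAsFactors = FALSE)
  out
}
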
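---
title: "Methods: two-sample MR screening of lipid species against colorectal cancer risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening of lipid species against colorectal cancer risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Total and LDL cholesterol are composite traits: each aggregates many
individual lipid species. Observational and genetic evidence links both
to colorectal cancer (CRC) risk, but composites cannot say *which*
species carries the risk. `lipidmr` implements the study design that
addresses this with GWAS summary statistics alone:

1. a **forward two-sample MR screen** of every lipid species against CRC
   in several independent case-control cohorts;
2. a **random-effects meta-analysis** of the per-cohort causal estimates
   for lipids significant in two or more cohorts;
3. a **reverse MR** check that CRC liability does not causally move the
   implicated lipids; and
4. a **two-step MR mediation** analysis asking how much of the
   cholesterol-to-CRC effect is routed through each implicated lipid.

Everything operates on per-SNP association records (beta, SE, allele
pair, allele frequency, p, N) — no individual-level data. Binary-outcome
effects are carried internally on the log-odds scale; odds ratios appear
only at reporting boundaries.

# The estimators

For harmonized instrument $i$ let $\hat\beta_{Xi}, \hat\beta_{Yi}$ be
the exposure and outcome associations with SEs
$\sigma_{Xi}, \sigma_{Yi}$, and $w_i = \sigma_{Yi}^{-2}$.

* **Wald ratio**: $\hat\theta_i = \hat\beta_{Yi}/\hat\beta_{Xi}$ with
  first-order SE $\sigma_{Yi}/|\hat\beta_{Xi}|$. Exposure uncertainty is
  ignored, as in conventional IVW weighting; a second-order SE is
  available behind the `second_order` flag of `wald_ratio()`.
* **IVW**: weighted regression of $\hat\beta_Y$ on $\hat\beta_X$ through
  the origin,
  $\hat\theta = \sum w_i \hat\beta_{Xi}\hat\beta_{Yi} / \sum w_i \hat\beta_{Xi}^2$,
  fixed-effect SE $(\sum w_i \hat\beta_{Xi}^2)^{-1/2}$. The
  multiplicative-random-effects (MRE) variant inflates the SE by
  $\sqrt{\max(1, Q/(k-1))}$, so it never undercuts the fixed SE.
* **MR-Egger**: the same regression with a free intercept after
  orienting all $\hat\beta_{Xi} \ge 0$; a non-zero intercept estimates
  directional pleiotropy, the slope remains a causal estimate under
  InSIDE. Both SEs carry the $\sqrt{\max(1, Q/(k-2))}$ inflation.
* **Weighted median / weighted mode**: consensus estimators over the
  per-SNP Wald ratios with inverse-variance weights
  $(\hat\beta_{Xi}/\sigma_{Yi})^2$; SEs by parametric bootstrap.
* **Cochran's Q** about a reference slope, $\chi^2_{k-1}$ (IVW) or
  $\chi^2_{k-2}$ (Egger); p < 0.05 flags heterogeneity.
* **MR-PRESSO**: leave-one-out weighted residual sum of squares,
  compared to a simulated null; per-SNP outlier p-values with Bonferroni
  flagging. Flagged SNPs are removed and the suite refit once (not
  iterated to convergence — bounded runtime, standard practice).

**Primary-estimate rule.** Reporting uses MR-Egger when its intercept
signals directional pleiotropy, otherwise MRE-IVW under heterogeneity,
otherwise fixed-effect IVW. "Signals pleiotropy" is read as the
*compound* negation of a no-pleiotropy declaration of the form
"intercept < 0.01 with p > 0.05": both `intercept_p < 0.05` and
`|intercept| >= 0.01` are required. This is an interpretive choice —
a p-value alone can flag an intercept too small to matter.

# Instrument selection

The chain, in order: exposure significance (forward p < 5e-6, reverse
p < 5e-8, strict), greedy LD clumping (r² < 0.001 within 10,000 kb;
p-ties broken lexicographically by SNP id so output is deterministic;
SNPs absent from the LD panel are treated as unlinked), harmonization,
removal of outcome-associated SNPs (p < 5e-5, recomputed two-sided
normal), Steiger directionality filtering, MR-PRESSO outlier removal.
Per-SNP provenance flags partition every candidate, and the per-SNP F
statistic $(\hat\beta_X/\sigma_X)^2$ is reported as a strength
diagnostic but never used as a filter.

Steiger's variance explained uses the $t^2/(t^2+n-2)$ approximation for
both continuous and log-odds traits; the formula is isolated in one
function so a different binary-trait approximation can be swapped in.

**Harmonization.** Records are aligned to the exposure's effect allele;
swaps negate the outcome beta and complement its frequency, strand
flips complement alleles. Palindromic (A/T, C/G) SNPs are oriented by
allele frequency only when both minor-allele frequencies fall below
0.42 (a conventional ceiling; the orientation is untrustworthy near
0.5) and dropped otherwise. Unreconcilable allele pairs are dropped
with their own action code. Harmonization is idempotent, and the action
log partitions the SNP intersection exactly.

**Outcome-association filter and strong effects.** Removing instruments
associated with the outcome at p < 5e-5 guards against direct outcome
effects, but it is calibrated for disease outcomes with modest causal
effects: if the true effect is strong and the outcome GWAS large, the
filter preferentially removes the *strongest valid* instruments and the
conditioning biases the estimate downward. Two consequences in this
package: the exposure-to-mediator leg of the mediation stage disables
the filter (a strong genuine instrument-mediator association is the
point there, not a red flag), and the estimator-level recovery studies
characterize the estimators without it.

# Meta-analysis

DerSimonian–Laird: fixed weights $w_i = s_i^{-2}$, $Q$ about the fixed
pooled value,
$\hat\tau^2 = \max(0, (Q - (k-1))/(\sum w - \sum w^2/\sum w))$, then
random weights $(s_i^2 + \hat\tau^2)^{-1}$. Chosen over REML for being
the closed-form, conventional "random effects model". Pooling is always
on the log-OR scale — pooling ORs directly would be scale-incoherent —
and converts to OR only in the forest table.

# Two-step mediation

With $a$ (exposure→mediator), $b$ (mediator→outcome) and $c$ (total
exposure→outcome) from three separate MR fits: indirect $= ab$, direct
$= c - ab$ (the identity indirect + direct $= c$ holds by
construction), proportion mediated $= ab/c$. SEs are first-order delta
method with $a, b, c$ independent — no covariance is estimable from
non-overlapping summary data; this is a documented limitation, not an
approximation choice. The mediation test is the Wald z of the
proportion with a symmetric normal 95% CI; symmetric intervals around a
reported proportion are the signature of exactly this construction.

The second step uses the mediator's own instruments *excluding* any SNP
that reaches the exposure's instrument threshold in the exposure GWAS
(disjoint-instrument two-step MR). Without this, instruments acting on
the outcome through the exposure's direct path contaminate $b$ — a
mediator-instrumented fit over shared instruments estimates
$\theta/a$, not $b$. Multivariable MR would adjust instead; it is out
of scope here, and the exclusion achieves the same goal for instruments
that are cleanly separable. The option `exclude_exposure_snps = FALSE`
restores the naive behaviour.

Degenerate inputs: a total effect within $10^{-12}$ of zero is refused
(the proportion is undefined); if $ab = 0$ the delta formula for the
proportion collapses, and the product SE divided by $|c|$ is used so a
zero indirect effect still gets a finite SE.

# The synthetic-GWAS generator

`simulate_triplet()` realizes the mediation graph
exposure → mediator → outcome with an additional direct
exposure → outcome path. Per SNP, the *estimated* beta is the true beta
plus Gaussian noise with SD $1/\sqrt{2p(1-p)n}$ — the standardized-trait
approximation under which public summary statistics scale — and the
*reported* SE equals that SD, making SEs a deterministic function of
the configuration. The three traits draw noise independently
(non-overlapping samples, as the two-sample design assumes). The
outcome is generated directly on the log-odds scale (linear
approximation) rather than through individual-level logistic
simulation: two-sample MR only ever sees summary statistics.
Horizontal pleiotropy is added to outcome betas of exposure instruments
only, independent of instrument strength, so InSIDE holds by default; a
`correlated_pleiotropy` switch violates it for robustness studies.

Default choices, made once:

* `effect_sd = 0.2` (trait SD per allele): the strong-instrument regime
  of molecular-trait GWAS, whose lead loci have much larger per-allele
  effects than polygenic disease traits. At the default n = 100k this
  gives mean F in the hundreds, so the first-order estimators' known
  O(1/F) attenuation is negligible against Monte-Carlo error.
* `effect_sign = "positive"`: instrument effects are half-normal, i.e.
  all instruments raise their trait. Effect-allele coding is arbitrary
  in real data, but a *directional*-pleiotropy analysis presumes a
  coherent orientation; with sign-symmetric effects, directional
  pleiotropy cancels out of both the IVW bias and the oriented Egger
  intercept and the scenario becomes vacuous.
* `n_snps_mediator`: mediator-specific instruments, without which the
  mediator→outcome path is not identifiable from the generator's graph.
* `maf_range = (0.05, 0.5)`: common variants, as instrument panels are.

What the generator does *not* emulate: LD between instruments (clumping
is exercised against user-supplied LD matrices), sample overlap between
the two samples, allele-frequency estimation error, population
stratification, and case-control ascertainment effects on the log-odds
scale. Recovery of known parameters here therefore validates the
estimators and the plumbing, not robustness to those real-data
features.

# Replicated studies and problem sizes

The calibration/recovery battery (`mr_calibration_study()`,
`presso_spikein_study()`, `mediation_recovery_study()`,
`meta_recovery_study()`) is what `analysis/06_calibration.R`, the
acceptance tests and `scripts/acceptance.R` run. Sizes, chosen as the
smallest that make the Monte-Carlo bands meaningful:

* null calibration: 50 SNPs, n = 100k per trait, 1000 replicates;
* effect recovery: as above but n = 500k (modern lipid-GWAS scale;
  at this depth the first-order attenuation sits an order below the
  2-Monte-Carlo-SE band), 1000 replicates, plus 500 replicates with
  directional pleiotropy (mean 0.05, SD 0.02);
* MR-PRESSO spike-in: one SNP offset by 10 outcome SEs among 50, 100
  replicates of 1000 null simulations (global-p resolution 1/1001);
* mediation recovery: 50 + 50 instruments, a = 0.5, b = 0.4, total
  0.25 (true proportion 80%), 500 replicates;
* meta-analysis recovery: 4 cohorts, true log-OR 0.15, between-cohort
  SD 0.05, within-cohort SE 0.02, 500 replicates. The within-cohort SE
  must sit well below the between-cohort SD here: with only four
  cohorts and comparable within-cohort noise, the truncated DL moment
  estimator's positive bias at $\tau^2 \approx 0$ would swamp any
  recovery criterion — identifiability, not convenience, fixes this
  constant.

The calibration study applies the workflow's own instrument-significance
selection before estimation. Besides being what the screen actually
does, this guarantees instruments have well-determined effect signs;
unselected near-zero-effect SNPs otherwise get mis-oriented by Egger's
sign convention and drag the intercept.

# Numerical conventions

* Two-sided normal p-values throughout, floored at 1e-300 so extreme
  associations survive the (0, 1] validity check.
* 95% CIs are symmetric normal on the estimation scale.
* Weighted median: the ratio whose cumulative normalized weight
  straddles 0.5; when 0.5 falls exactly on the boundary between two
  SNPs' mass, their midpoint. A SNP holding the majority of the weight
  therefore returns its own ratio exactly.
* Weighted mode bandwidth: `phi * 0.9 * min(sd, mad) * k^(-1/5)`;
  degenerate spread (all ratios equal) returns the common value.
* All randomized components (generator, bootstraps, MR-PRESSO) take
  explicit seeds; the pipeline derives per-pair seeds from one base
  seed, so every stage is reproducible bit for bit.
* Clumping tie-break and the sorted SNP order after harmonization make
  results invariant to input row order.

# Known limitations

Plain two-step mediation (no MVMR adjustment of $b$); no SIMEX or
penalized Egger variants; no LD-panel computation (bring your own
r-squared matrix); no proxy-SNP search or liftover; the reverse
direction reports estimates but no formal bidirectional test; and the
delta-method proportion CI can legitimately exceed [0%, 100%] when the
total effect is imprecise, as published mediation tables also show.
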
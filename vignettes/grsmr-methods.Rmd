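---
title: "Allele-score Mendelian randomization with grsmr: models, assumptions and design choices"
author: "grsmr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-score Mendelian randomization with grsmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the causal model, the tunable parameters and their defaults,
what the cohort simulator does and does not emulate, the numerical choices,
and the design decisions that were genuinely open.

## The causal model

Mendelian randomization treats genetic variants as instruments for a
modifiable exposure. `grsmr` implements the weighted allele-score variant of
the design for a binary outcome: with per-allele GWAS effects $\beta_j$ on
the standardized log exposure and harmonized effect-allele dosages
$g_{ij} \in [0,2]$, the per-individual relative exposure is

$$s_i = \sum_j \beta_j g_{ij},$$

and the causal log odds ratio per SD of log exposure is the coefficient
$\theta$ of $s_i$ in a maximum-likelihood logistic regression of case
status on $s_i$ plus covariates. Because each $\beta_j$ is already in
per-allele SD units, the weighted sum is used directly as the exposure
proxy: there is no division by $\sum_j \beta_j$ and no within-cohort
re-standardization. Re-standardizing would silently change the "per SD"
interpretation of the reported OR, which is the quantity everything else
(power, meta-analysis, comparisons across strata) is expressed in.

The design's validity assumptions are the usual MR triple: the variants are
(i) associated with the exposure, (ii) independent of confounders of the
exposure–outcome relation, and (iii) affect the outcome only through the
exposure. Assumption (ii) is checkable with individual-level data and is
exposed as `confounderBalance()`; (iii) is probed indirectly by
`leaveOneOut()` and `allSubsets()`.

## Instrument strength

Under Hardy–Weinberg and linkage equilibrium a score on a unit-variance
exposure explains

$$R^2 = \sum_j \beta_j^2 \, 2 p_j (1-p_j),$$

which `expectedInstrumentR2()` evaluates; the packaged five-variant 25OHD
instrument gives 0.0438, inside the 3–5% band reported for these variants.
Pairwise independence of the instrument variants is an *input contract*:
the package performs no LD pruning, and correlated instruments will
overstate $R^2$ and understate standard errors.

## Harmonization

Two-sample designs must reconcile the allele a cohort dosage counts with
the weight's effect allele. `harmonizeDosages()` resolves the four
orientation cases (identity, swap $d \mapsto 2-d$, strand flip, swap+flip)
from the allele pairs alone; the twelve non-palindromic ordered pairs are
enumerated against a hand-built truth table in the test suite. Palindromic
(A/T, C/G) pairs cannot be strand-resolved from alleles; the default policy
drops them with a warning, and `palindromic = "infer"` resolves them by
comparing cohort allele frequency with the weight EAF. One of the five
packaged variants (the CYP24A1 variant, alleles T/A) *is* palindromic, so
pipelines reading it from VCF should use the inference policy — its EAF of
0.79 is far from 0.5, making frequency-based inference unambiguous.
Dosage-table input is defined as already effect-oriented and skips
harmonization. After harmonization an EAF discordance above 0.2 between
weights and cohort triggers a warning.

Missing dosages null an individual's score by default (conservative,
explicit); `impute_missing` substitutes the HWE mean $2p_j$ instead. Both
hard-call and expected (fractional) dosages are accepted, since real
cohorts mix genotyped and imputed variants.

## Weight-imprecision bootstrap

The naive SE of $\hat\theta$ conditions on the $\beta_j$ being known.
`bootstrapWeightCorrection()` propagates their uncertainty with a
parametric bootstrap: per replicate, $\beta^*_{jb} \sim N(\beta_j, SE_j)$
independently across variants (no GWAS covariance matrix is published for
these weights, so independence is the only available choice), the score is
rebuilt, the model refit, and

$$se_{corrected} = \sqrt{se_{naive}^2 + \mathrm{Var}_b(\hat\theta^*_b)}.$$

The point estimate stays at the original-weight fit; CI and p-value are
recomputed from the corrected SE. The variance-addition form is the
default because it directly operationalizes "extra uncertainty from the
weights"; the alternative of using the replicate SD alone
(`method = "replicate-sd"`) is available but degenerate in the common case
where weight imprecision is a small fraction of sampling noise, since the
replicate SD then falls *below* the naive SE. With B at its default of
1,000 the correction is stable to well under 1% between runs; because the
correction term for these weights is an order of magnitude smaller than
the naive SE, the package's own long-running calibration tests use B of
25–50, which leaves coverage unchanged.

Replicates that fail to converge are dropped with a warning; more than 10%
dropped is an error, since the bootstrap distribution is then no longer
trustworthy.

## Meta-analysis

`dlRandomEffects()` is a direct transcription of the DerSimonian–Laird
method-of-moments estimator: $w_i = 1/se_i^2$, Cochran's $Q$,
$\tau^2 = \max(0, (Q-(k-1))/(\sum w - \sum w^2/\sum w))$, random-effects
weights $1/(se_i^2+\tau^2)$, z-based CIs. The package uses z-based rather
than Hartung–Knapp intervals, consistent with the symmetric intervals this
kind of analysis conventionally reports. $I^2 = \max(0,(Q-df)/Q)$ carries a
Higgins–Thompson test-based interval on $\ln H$; for $k = 2$ with $Q \le k$
that SE is undefined and the interval is returned as `NA`. A single
estimate is returned unpooled with a warning rather than erroring, so
stratified pipelines degrade gracefully. The implementation is verified
against both a literal re-transcription and `metafor::rma(method = "DL")`
to $10^{-12}$. `seFromCI()` back-derives log-scale SEs from printed
OR/CI triples so published summary estimates can be pooled without
individual-level data.

## Power

`detectableOR()`/`powerAtOR()` implement the standard normal approximation
for score-based MR with a case-control outcome:

$$b = \frac{z_{1-\alpha/2} + z_{power}}{\sqrt{N R^2 \phi(1-\phi)}},$$

with case fraction $\phi$. This is the binary-outcome approximation behind
the widely used online MR power calculators; reproducing the published
detectable-OR bounds (0.74 and 0.79 at $R^2$ = 0.03 and 0.05 for 5,133
cases / 5,984 controls) from printed inputs validates the formula choice.
The two functions are exact inverses, asserted to $10^{-10}$.

## The cohort simulator

`simulateCohort()` generates the case-control structure the estimator
assumes, so every downstream stage is testable without restricted data:

* **Genotypes**: $g_{ij} \sim \mathrm{Binomial}(2, p_j)$ independently
  across variants — Hardy–Weinberg and linkage equilibrium by
  construction.
* **Exposure**: $x_i = s_i - E[s] + \epsilon_i$ with noise SD
  $\sqrt{1-R^2}$, so $x$ has unit variance and the instrument explains
  exactly the analytic $R^2$. The exposure lives directly on the
  standardized log scale (the scale of the causal OR); raw concentration
  units are out of scope.
* **Outcome**: $\mathrm{logit}\,P(\text{case}) = \alpha + \theta x_i +$
  confounder terms, with $\alpha$ defaulting to logit(0.15). Cases and
  controls are then sampled retrospectively from a source population
  `pop_mult` (default 4) times the target size, matching a case-control
  design; logistic slopes are invariant to outcome-dependent sampling, so
  $\theta$ remains the estimand. If the population cannot supply the
  requested counts the error suggests raising `alpha` or `pop_mult`.
* **Composition**: per-stratum counts default to the three-region
  consortium the package emulates (Europe 2,323/2,928, North America
  2,254/2,329, South America 556/727; 11,117 in all), cases split
  oral:oropharyngeal 52.6:47.4, and sex, age band, smoking and alcohol are
  drawn from that consortium's published marginal frequencies,
  independent of genotype — so instrument–confounder balance tests have a
  true null. Principal components are standard normal with a stratum mean
  offset on PC1 (0.5 per stratum index), giving the covariate adjustment
  something real to absorb.

Determinism: the RNG kind is pinned inside `simulateCohort()`, so a config
and seed identify a cohort exactly; `packagedFixture()` exploits this to
regenerate its ~2,000-sample three-region cohort on demand from an
embedded config and fixed seed instead of shipping a data file.

**The structure scenario.** The artifact the simulator reproduces is a
spurious stratum-specific causal OR driven by population structure. A
stratum-level allele-frequency shift plus a stratum-level risk shift
cannot produce it: within-stratum regressions absorb stratum main effects
into the intercept. What does produce it is *sub*-stratum structure, so
`structure_scenario = TRUE` plants a latent subpopulation (fraction 0.5)
inside `structure_stratum` whose genotype EAFs are shifted by
`eaf_shift / subpop_fraction` (making the *stratum-level* mean shift equal
the configured `eaf_shift`, default +0.10 on the two largest-effect common
variants) and which carries `structure_log_or` (default log 5) on the
outcome logit. Allele frequency then co-varies with risk within the
stratum, and the within-stratum score–outcome regression picks up a
confounded slope of roughly
$\Delta s \cdot f(1-f) \cdot \text{structure\_log\_or} / \mathrm{Var}(s)
\approx 1.3$ log-OR units — an apparent OR near 4 in the structured
stratum, of the magnitude such artifacts reach in practice — while the
other strata stay null. Excluding the stratum removes the heterogeneity,
which is exactly the diagnostic-and-resolution loop the pipeline's
`exclude_stratum` option automates. These magnitudes are illustrative
defaults, not calibrated claims about any real population.

**What the simulator does not emulate**: linkage disequilibrium between
instrument variants, genotyping/imputation error, HPV status or other
site-specific aetiology, study-level (as opposed to region-level)
clustering, and confounders that actually correlate with genotype. Passing
tests therefore demonstrate internal statistical correctness of the
estimator chain under the design's own assumptions — not robustness to
violations of those assumptions in real data.

## Numerical choices

* Logistic fits use IRLS (`stats::glm.fit`) with deviance tolerance
  $10^{-8}$ and at most 100 iterations; bootstrap refits warm-start from
  the original-weight solution. Non-convergence, rank deficiency and
  (quasi-)separation (any |coefficient| > 20) are errors naming the
  stratum being fit.
* Wald (normal) CIs and p-values throughout, matching the symmetric
  intervals the design conventionally reports.
* $\tau^2$, $I^2$ and the detectable-OR formulas are closed-form; the only
  truncations are $\tau^2 \ge 0$, $I^2 \in [0,1]$ and $H \ge 1$.
* Degenerate inputs: constant scores, single-level covariates, empty
  strata, zero-SE weights and single-estimate pooling all have defined
  behaviour (error, warning-and-skip, or exact fall-through) covered by
  tests.

## Problem sizes used in validation

The long-running calibration tests simulate at the full default cohort
scale (11,117 participants): 300 seeds (100 per causal OR in {1, 0.8,
1.3}) with a 25-replicate bootstrap for bias and CI coverage, 500 seeds
for the null type-I error and balance-uniformity checks, and 100 seeds for
the structure-artifact scenario. These sizes were chosen so that Monte
Carlo noise is small relative to each acceptance band while the whole
suite stays comfortably runnable on a laptop.

## Known limitations

* One estimator: allele-score logistic regression. Ratio/2SLS, MR-Egger
  and weighted-median estimators are out of scope (with five variants
  they would be severely underpowered anyway).
* REML/Paule–Mandel $\tau^2$ and Hartung–Knapp intervals are not
  implemented; DerSimonian–Laird is the deliberate, conventional choice.
* No BGEN/PLINK input; VCF and dosage TSV only.
* The bootstrap assumes independent weight errors across variants.
* Power formulas are asymptotic normal approximations; they agree with
  simulation through the estimator to within Monte Carlo error in the
  test suite, but are not exact at small n or extreme case fractions.
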
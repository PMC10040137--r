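---
title: "Methods: paired mother-newborn methylome analysis in duomethyl"
author: "duomethyl maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired mother-newborn methylome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duomethyl)
```

# Overview

`duomethyl` analyses matched maternal and neonatal whole-blood DNA
methylation: sample-wise similarity of paired methylomes against a
permutation background, per-site regression scans of the mother-newborn
association and of the mother-newborn methylation *difference* on newborn
sex, surrogate-variable adjustment, replication concordance, and
annotation/heritability/pathway summaries. A synthetic cohort generator
with known truth underpins every test. This vignette records the models,
the tunable parameters, the numerical choices, and the limits of what the
synthetic validation can show.

# The synthetic cohort model

## Generative scale

Beta values are generated on the logit scale and mapped through the
inverse logit, which keeps them bounded in (0,1) and makes heritability
interpretable as a variance fraction on the modelling scale. For site $j$
and mother $i$:

$$\mathrm{logit}(\beta^{M}_{ij}) = \mu_j + a_j\,(\text{age}_i - \bar{\text{age}})
 + g^{M}_{ij} + \sum_k \lambda_{jk} L^{M}_{ik} + \varepsilon_{ij},$$

with $\mathrm{Var}(g^{M}) = h^2_j\,\sigma^2$ and
$\mathrm{Var}(\varepsilon) = (1-h^2_j)\,\sigma^2$, where $\sigma$
(`noiseSD`, default 0.5 logit units) is the total per-site biological SD.
The newborn's genetic value is

$$g^{C} = \tfrac12\,g^{M} + r, \qquad \mathrm{Var}(r) = \tfrac34\,\mathrm{Var}(g^{M}),$$

the additive model with an unobserved father: mother and child then share
genetic correlation 1/2 and the logit-scale mother-child correlation at a
site is $h^2_j/2$. This closed form is the oracle for the
parameter-recovery checks (mean observed correlation 0.40 at $h^2 = 0.8$).
Male newborns add a per-site `sex_effect` (drawn N(0, `sexEffectSD`),
default SD 0.3 logit units) at a `fracSexDifferential` (default 5%)
subset of autosomal sites.

## X inactivation

A fraction `fracXInactivated` (default 0.75) of X sites is modelled as
subject to X-inactivation with balanced (unskewed) choice of the silenced
copy. Their active-allele mean $\mu_j$ is drawn promoter-island-like
(low, mean logit −2.5) and the inactive-allele mean sits
`muInactiveOffset` above it (default mean +3, SD 0.5 logit units —
predominantly methylated). Mothers and female newborns emit the
equal-weight allele average
$\tfrac12(\mathrm{expit}(z_{\text{active}}) + \mathrm{expit}(z_{\text{inactive}}))$;
males emit the single active draw. Two consequences follow and are
asserted directionally in the tests: mother-male X differences
($\Delta = \beta^C - \beta^M$) are negative while mother-female
differences sit at zero, and cross-site rank profiles of mothers and
daughters agree better than mother-son profiles, depressing mother-male
X-chromosome Spearman correlations. The remaining X sites ("escape")
behave autosomally.

## Latent structure and the pair sheet

`nLatentFactors` (default 3) latent batch/cell-composition factors load
on every site with N(0, `loadingSD` = 0.3 logit) coefficients; mother and
newborn scores are independent by default (`sharedLatentScores = FALSE`
mimics separate array placement; TRUE mimics co-placement). The paper's
cohorts do not quantify mother-child environmental sharing, so no value
is asserted; the switch is the exposed free parameter. The simulated pair
sheet emulates an urban birth-cohort design: 54.5% male newborns,
maternal age uniform over `maternalAgeRange` (15–46 years), ~65% Black
mothers, ~11% smoking, sex-specific preterm rates (20.8% male / 11.1%
female), ~31% C-section, parity 1/2/3+.

The default heritability distribution is a mixture — 60% of sites from
Uniform(0, 0.05) (effectively null) and 40% from Uniform(0.05, 0.95) —
mimicking the long right tail of published methylation-QTL heritability
without reproducing any catalogue.

## What the generator does not emulate

Array chemistry (type I/II probe bias, dye bias), imprinting, skewed XCI,
paternal genomes, cell-type deconvolution targets, and genomic
autocorrelation between neighbouring sites. Passing tests therefore
demonstrate the statistical machinery under the stated model, not
robustness to array artefacts; on real data the QC filters and surrogate
variables carry that weight.

# Quality control and transformation

Sites are removed when their detection p-value exceeds 0.01 in strictly
more than 5% of samples, or when listed in a user-supplied mask
(SNP-overlapping / cross-hybridizing probes — supplied as a file because
these are published lists, not an algorithm). Samples are removed when
missing strictly more than 2% of sites, or when methylation-predicted sex
(a 1-D two-means split of the mean X-chromosome beta, females higher
under allele averaging) disagrees with the recorded sex. Both thresholds
are read as strict inequalities ("over 5%", "> 2%").

The inverse normal transformation maps values to
$\Phi^{-1}\{(r - 3/8)/(n + 1/4)\}$ with average ranks for ties — the Blom
offset, the conventional choice where no particular rank-to-normal map is
mandated. INT is applied per site to the non-missing values; sites with
constant values are flagged rather than dropped silently.

# Pairwise correlations and the permutation background

Spearman's rho per pair is computed over all shared sites and the
autosomal/X subsets (average ranks for ties; pairwise deletion of missing
values). The no-relatedness background preserves the between-site
correlation structure: within each newborn-sex stratum a derangement
reassigns newborns to unrelated mothers; with `nIter = 10` iterations the
per-newborn background value is the across-iteration mean (not the pooled
set). Derangements are drawn by rejection sampling, which is exact and
fast (acceptance probability ≈ 1/e). Matched vs background uses the
paired t test on per-pair differences, with a degenerate-variance flag
(p = 1) when all differences are zero. Between-sex comparisons use the
Welch form — only "two-sample t test" is specified, and unequal variances
are the safe default; the variant is recorded in the output.

Computationally, with complete matrices each subset is rank-standardized
once and all matched and shuffled coefficients come from one cross-product
matrix per sex stratum, so 10 iterations cost no more than the matched
pass.

# Surrogate variables

**Number of components.** Parallel analysis: residualize the outcome on
the model (including the protected exposure when there is one), compare
each observed residual singular value with the
$\lceil (B+1)\,0.95 \rceil$-th order statistic of the corresponding
singular values from $B = 20$ permutations. The raw outcome is permuted
within rows and re-residualized, so both arms pass through the same
projection; the order-statistic threshold makes the per-component
exceedance probability exactly $\le 5\%$ under the null. K is the number
of leading components exceeding their threshold. No component-count rule
is claimed by the source analyses (their 36/37 are data-determined), so K
is data-driven here with a fixed-K override (`nSv`).

**Scores.** Iteratively re-weighted residual SVD. The starting basis is
the top-K right singular vectors of the *full-model* residual (covariates
plus protected exposure), so it contains no exposure signal. Each
iteration scores every site with two F statistics — association with the
current surrogate variables ($F_{sv}$) and with the penalized block
($F_{cov}$: the clinical covariates, or the protected exposure when one
is declared) — and forms weights $w_j = F_{sv}/(F_{sv}+F_{cov}+1)$, a
monotone bounded surrogate for posterior-probability weights. The SVD is
recomputed on the row-weighted *covariate-only* residual, and iteration
stops when the principal angle between successive subspaces changes by
less than `tol` (1e-4; `maxIter` 50, non-convergence returns the best
iterate with a warning). Scores are centered and orthonormalized.

**Why the exposure is protected this way.** For the Δ ~ sex analysis,
three designs were evaluated on simulated cohorts. Putting sex into the
residualization design makes the surrogate variables exactly orthogonal
to sex; they then remove latent-factor variance while leaving the
finite-sample latent-by-sex correlation in place as bias, inflating null
autosomal tests (genomic inflation ≈ 1.9 at 400 pairs). Weight-only
protection starting from a covariate-only residual fails in the opposite
direction: with strong X-inactivation structure the first singular vector
*is* sex, and the weights can no longer tell exposure from confounder.
The implemented design — exposure-free initialization, exposure-block
penalty in the weights, SVD on the weighted covariate-only residual —
recovers confounders *including* their realized correlation with sex
through sites the weights certify as non-signal. On the X-inactivation
simulation it restores the null inflation factor to ≈ 0.92 and agrees
with adjusting for the true latent scores; an independent run of the
reference implementation in the `sva` package behaves identically (used
in the test suite as a cross-check only).

# The two EWAS scans

**Site association.** Per site, maternal and neonatal vectors are
INT-transformed separately; the reduced model is
`neonatal ~ sex + covariates + SVs` and the full model adds the maternal
main effect, maternal×sex, and maternal×covariate interactions (SVs enter
as main effects only, following the printed model formula). The LRT uses
the Gaussian profile form $n\log(\mathrm{RSS}_r/\mathrm{RSS}_f)$ with df
equal to the exact column difference (7 with the five standard clinical
covariates); the interaction p-value is the Wald t of the maternal×sex
coefficient, algebraically identical to the single-constraint F test.
Clinical covariates are maternal age (years), race (Black/non-Black),
smoking, preterm birth and delivery type, with parity as an optional
toggle for the sensitivity analysis. Pairs with missing values are
dropped listwise per site and counted; rank-deficient sites are flagged
with missing statistics.

**Difference EWAS.** Raw-beta Δ feeds the descriptive summaries (pooled
over site × pair observations, by sex × chromosome class); the
regression uses INT(Δ) on sex + covariates + Δ-outcome SVs. The design is
shared across sites, so complete sites are fit in a single
multi-response least-squares pass.

BH-FDR is computed jointly across autosomes and X in both scans (the
source analyses count all sites in one FDR), and the interaction FDR
likewise spans all tested sites — whether it should be restricted to
LRT-significant sites is not specified anywhere, so the joint choice is
recorded in the result metadata.

# Replication, annotation, enrichment

Replication joins discovery-significant sites onto a second cohort's
results by site ID (refusing to join when sex codings disagree),
recomputes BH-FDR within the overlapping set, and tests the
direction-agreement split against 50:50 with a 1-df Pearson goodness-of-
fit chi-square — the concordance test's exact contingency structure is
not published, so the 50:50 null is the documented interpretation.
Percentages print half-up to one decimal.

Heritability stratification ranks autosomal sites by p-value and
compares the median h² of the top `topN` (default 100) with the
background median ("median" is the documented reading of the source's
"medium h²"). Pathway over-representation is a one-sided upper-tail
hypergeometric test against user-supplied GMT sets, with the universe
defaulting to all genes mappable from the analyzed sites — the
conservative EWAS background; the proprietary pathway tool used by the
source is not reproduced, so its printed enrichment p-values are not
comparison targets.

# Numerical choices and degenerate inputs

- Betas are clipped to (1e-6, 1−1e-6); Δ values lie in [−1, 1].
- Spearman uses average ranks; INT uses average ranks with the Blom
  offset; constant vectors raise explicit errors (matrix wrappers flag
  the site instead).
- The LRT is invariant to affine rescaling of covariates (asserted to
  1e-8 in the tests); the Wald/F identity is asserted to 1e-10.
- kmeans for sex prediction is initialized at the observed min/max, so
  it is deterministic.
- One global seed fans out to per-stage seeds via a fixed integer hash,
  keeping stages independently re-runnable yet reproducible; all derived
  seeds stay below 2^31.

# Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to finish in minutes while
leaving clear margins: null calibration uses 10 cohorts of 2,000 sites ×
300 pairs; parameter recovery 2,000 sites × 300 pairs (the rank-tracking
check draws h² uniformly over (0, 0.95), because ordering *within* the
default mixture's near-zero mass is sampling noise at 300 pairs); the
X-inactivation pattern 5,000 sites × 400 pairs; surrogate-variable rescue
2,000 null sites × 200 pairs with a sex-correlated batch shifting 40% of
sites by 0.05 beta units. Genome-scale discovery counts from the
motivating cohorts depend on restricted data and are covered
directionally, not numerically.

# Known limitations

- The Gaussian OLS likelihood underlies the LRT; heavy-tailed residuals
  are tamed by INT rather than robust errors.
- Exposure-protected surrogate variables cannot, even in principle,
  remove confounding that is *population*-correlated with the exposure;
  the batch-rescue demonstration works because the injected batch is
  identified from sites the weights certify as non-signal.
- The generator's independence of neighbouring sites overstates the
  effective number of independent tests relative to real arrays.
- Pooled Δ summaries average over site × pair observations; per-site
  averaging first would weight sites equally (the source's pooling choice
  is not stated; ours is labelled in the output).
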
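# duomethyl

Analysis of the intergenerational link between maternal and neonatal
whole-blood DNA methylation in matched mother–newborn pairs, with
particular attention to differences by newborn sex.

## The scientific problem

DNA methylation (DNAm) at a CpG site is summarized by a beta value — the
methylated fraction, in [0, 1] — measured genome-wide on arrays for both
a mother and her newborn's cord blood. Two questions drive the analyses
here:

1. **How similar are paired mother–newborn methylomes, and does the
   similarity differ by newborn sex?** Per pair, Spearman's rho is
   computed across all shared sites (and the autosomal and X-chromosomal
   subsets separately) and compared with a *background* of deliberately
   mismatched pairs: within each newborn-sex stratum, newborns are
   reassigned to unrelated mothers by a derangement (no newborn keeps its
   own mother), the shuffle is repeated (10 iterations by default), and
   each newborn's background coefficient is its mean rho over iterations.
   A paired t test contrasts matched vs background; a Welch t test
   contrasts the sexes.

2. **Which individual sites link mother and newborn, and where do
   methylation levels differ by sex?** Per site, after a rank-based
   inverse normal transformation (INT) of each vector,

   - the *site association EWAS* compares a full model
     `neonatal ~ maternal + sex + maternal×sex + Σcovariate +
     Σmaternal×covariate + ΣSV` against a reduced model
     `neonatal ~ sex + Σcovariate + ΣSV` with a likelihood-ratio test
     (statistic `n·log(RSS_reduced/RSS_full)`, chi-square with df equal to
     the column difference), plus a Wald test of the maternal×sex
     interaction;
   - the *difference EWAS* regresses INT(Δ), where
     `ΔDNAm = DNAm_neonatal − DNAm_maternal`, on newborn sex
     (0 = female, 1 = male) plus covariates and surrogate variables.

   Benjamini–Hochberg FDR is applied jointly across autosomes and X.

Surrogate variables (SVs) absorbing batch, cell-composition and other
hidden structure are estimated by an iteratively re-weighted residual SVD
with a permutation parallel analysis choosing the number of components;
for the Δ analysis the newborn-sex exposure is *protected* so SVs cannot
absorb the tested effect.

X-chromosome inactivation (XCI) is the organizing biology: females
silence one X, and silenced island-promoter sites are predominantly
methylated, so a female beta value behaves like an average of an active
(unmethylated) and an inactive (methylated) allele while a male shows the
single active allele. This predicts — and the package's synthetic
generator reproduces — lower mother–male than mother–female X
correlations and negative mother–male ΔDNAm on inactivated X sites.

Because real cohort data are restricted, the package ships a synthetic
paired-methylome generator (`simulateCohort`): logit-scale beta values
with per-site heritability h² (an additive model giving mother–child
correlation h²/2), sex-differential autosomal sites, maternal-age drift,
latent batch factors, and the XCI allele-average model, plus a truth
table for every downstream test.

## Worked example

```r
library(duomethyl)

cfg <- cohortConfig(nPairs = 200, nAutoSites = 4000, nXSites = 1000,
                    seed = 42)
mps <- simulateCohort(cfg)
mps
#> MethylPairSet with 5000 sites and 200 mother-newborn pairs
#>   newborn sex: 91 female / 109 male
#>   sites: 4000 autosomal / 1000 X-chromosomal

pc <- pairSpearman(mps)
bg <- permutationBackground(mps, nIter = 10, seed = 43)
compareBySex(pc, subset = "x")[c("p", "group_means")]
#> $p
#> [1] 5.248012e-99
#> $group_means
#>    female      male
#> 0.8577923 0.6284728
```

Mother–female X-chromosome correlations (mean rho 0.86) are far stronger
than mother–male (0.63) — the XCI allele-average signature.

```r
d <- computeDelta(mps)
summarizeDelta(d, newbornSex(mps), isXSite(mps))
#>      sex chrom_group          mean         sd  n_obs
#> 1 female    autosome  0.0006212095 0.12335670 364000
#> 2   male    autosome  0.0004947264 0.12582910 436000
#> 3 female           X -0.0005780559 0.09839174  91000
#> 4   male           X -0.1857764037 0.16054831 109000
```

On the X chromosome, males are on average less methylated than their
mothers (pooled Δ mean −0.19) while mother–female differences sit at
zero; autosomes show no sex pattern. Regressing INT(Δ) on newborn sex
then finds discoveries almost exclusively on X:

```r
res <- runDeltaEwas(d, as.data.frame(pairData(mps)),
                    chromosome = siteAnno(mps)$chromosome)
table(chromosome = ifelse(res$chromosome == "X", "X", "autosome"),
      significant = res$significant)
#>           significant
#> chromosome FALSE TRUE
#>   autosome  3944   56
#>   X          250  750
```

`runFullPipeline(runConfig(cohort = cfg, outDir = "run1"))` executes the
whole chain — QC, paired correlations with permutation background, SV
estimation for both outcomes, both EWAS scans, cohort characteristics,
and optional replication-concordance and pathway over-representation
stages — writing TSV/JSON outputs and a checksummed manifest.

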
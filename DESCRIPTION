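Package: duomethyl
Title: Mother-Newborn Paired DNA Methylation Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the intergenerational link between maternal
    and neonatal whole-blood DNA methylation in matched mother-newborn
    pairs. Implements sample-wise Spearman correlation of paired methylomes
    against a sex-matched derangement permutation background, surrogate
    variable estimation by iteratively re-weighted residual SVD with
    permutation parallel analysis, per-site likelihood-ratio EWAS of the
    mother-newborn association with maternal-methylation-by-sex interaction
    tests, an EWAS of mother-newborn methylation differences on newborn
    sex, replication concordance summaries, annotation and heritability
    stratification, and hypergeometric pathway over-representation.
    Includes a synthetic paired-methylome generator with an additive
    genetic model and an X-inactivation allele-average model so the whole
    pipeline can be exercised with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    fgsea,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva
Config/testthat/edition: 3
biocViews: DNAMethylation, Epigenetics, BatchEffect, StatisticalMethod
RoxygenNote: 7.3.3
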
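# Gene mapping, category distributions, heritability strata, and
# hypergeometric over-representation.

toyAnno <- function() {
  data.frame(
    site_id = sprintf("cg%02d", 1:6),
    chromosome = c("1", "1", "2", "X", "X", "3"),
    gene = c("TP53", "TP53", "LOC158572;USP27X", "EFHC2", "", "BMP4"),
    functional_region = c("Body", "TSS200", "5'UTR", "Body", "intergenic",
                          "Body"),
    island_relation = c("Island", "Island", "N_Shore", "Island", "OpenSea",
                        "S_Shore"),
    h2 = c(0.9, 0.1, 0.5, NA, NA, 0.3),
    stringsAsFactors = FALSE)
}

test_that("sites map to deduplicated, semicolon-split gene sets", {
  anno <- toyAnno()
  expect_equal(mapSitesToGenes(c("cg01", "cg02"), anno), "TP53")
  expect_setequal(mapSitesToGenes("cg03", anno), c("LOC158572", "USP27X"))
  expect_length(mapSitesToGenes("cg05", anno), 0)  # intergenic only
  expect_error(mapSitesToGenes(c("cg01", "nope"), anno), "nope")
})

test_that("category distributions count over the full universe and sum to one", {
  anno <- toyAnno()
  d <- categoryDistribution(anno$site_id, anno, "functional_region")
  expect_equal(sum(d$proportion), 1, tolerance = 1e-12)
  expect_equal(d$count[d$category == "Body"], 3)
  expect_equal(d$count[d$category == "TSS200"], 1)
  expect_equal(sum(d$count), 6)
  one <- categoryDistribution("cg01", anno, "island_relation")
  expect_equal(one$proportion[one$category == "Island"], 1)
  expect_error(categoryDistribution(character(0), anno), "empty")
})

test_that("category comparison is the textbook Pearson chi-square", {
  a <- c(Island = 10, OpenSea = 0)
  b <- c(Island = 0, OpenSea = 10)
  res <- compareCategoryDistributions(a, b)
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)
  # scaling both rows by 10 multiplies the statistic by 10
  res10 <- compareCategoryDistributions(10 * a, 10 * b)
  expect_equal(res10$statistic, 200)
  # identical distributions: statistic 0, p 1
  same <- compareCategoryDistributions(c(A = 5, B = 7), c(A = 5, B = 7))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # categories with zero pooled count are dropped
  withZero <- compareCategoryDistributions(c(A = 5, B = 7, C = 0),
                                           c(A = 5, B = 7, C = 0))
  expect_equal(withZero$df, 1)
  expect_error(compareCategoryDistributions(c(A = 0), c(A = 0)), "zero")
  # hand-built 2x3 table against sum((O-E)^2/E)
  g1 <- c(A = 12, B = 3, C = 9)
  g2 <- c(A = 5, B = 11, C = 4)
  tab <- rbind(g1, g2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(compareCategoryDistributions(g1, g2)$statistic,
               sum((tab - E)^2 / E), tolerance = 1e-10)
})

test_that("heritability strata compare top-ranked sites to the background median", {
  anno <- data.frame(site_id = sprintf("cg%03d", 1:50),
                     chromosome = rep(c("1", "X"), c(40, 10)),
                     h2 = c(rep(0.4, 40), rep(NA, 10)))
  res <- data.frame(site_id = anno$site_id, p_lrt = runif(50))
  hs <- heritabilityStrata(res, anno, topN = 10)
  expect_equal(hs$median_h2_top, 0.4)
  expect_equal(hs$median_h2_background, 0.4)
  expect_equal(hs$n_background, 40)
  # invariant to row order
  perm <- sample(50)
  hs2 <- heritabilityStrata(res[perm, ], anno, topN = 10)
  expect_equal(hs, hs2)
  expect_error(heritabilityStrata(res, anno, topN = 100), "available")

  # generator-driven direction: LRT signal tracks h2, so top sites carry
  # higher heritability than the background
  cfg <- cohortConfig(nPairs = 150, nAutoSites = 500, nXSites = 20,
                      fracXInactivated = 0, h2Mixture = c(0.5, 0.05, 0.95),
                      nLatentFactors = 0L, seed = 101)
  mps <- simulateCohort(cfg)
  ewas <- runSiteEwas(mps)
  hsT <- heritabilityStrata(ewas, as.data.frame(siteAnno(mps)), topN = 50)
  expect_gt(hsT$median_h2_top, hsT$median_h2_background)
})

test_that("hypergeometric ORA equals exact enumeration on small universes", {
  universe <- letters[1:10]
  res <- hypergeometricOra(letters[1:4], list(pw = letters[1:5]), universe)
  expect_equal(res$p, 5 / 210)  # C(5,4)*C(5,0)/C(10,4)
  expect_equal(res$n_in_map, 5)
  expect_equal(res$n_in_data, 4)

  # pathway covering the whole universe is never enriched
  resAll <- hypergeometricOra(letters[1:4], list(pw = universe), universe)
  expect_equal(resAll$p, 1)
  # zero overlap: the upper tail from 0 spans everything
  res0 <- hypergeometricOra(letters[1:2], list(pw = letters[9:10]), universe)
  expect_equal(res0$p, 1)

  # enumeration oracle over random small cases
  set.seed(6)
  for (i in 1:50) {
    N <- sample(5:20, 1)
    uni <- sample(LETTERS, N)
    K <- sample(1:N, 1)
    q <- sample(1:N, 1)
    pw <- sample(uni, K)
    gs <- sample(uni, q)
    k <- length(intersect(pw, gs))
    got <- hypergeometricOra(gs, list(x = pw), uni)$p
    expect_equal(got, bruteForceHyper(k, K, N, q), tolerance = 1e-12)
  }
  expect_error(hypergeometricOra("a", list(), character(0)), "universe")
  expect_error(hypergeometricOra("zz", list(x = letters), letters), "outside")
})

test_that("GMT gene sets round-trip through the reader", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("pathA\tdesc\tTP53\tBMP4", "pathB\tdesc\tEFHC2"), path)
  gmt <- readGmt(path)
  expect_equal(gmt$pathA, c("TP53", "BMP4"))
  expect_equal(gmt$pathB, "EFHC2")
})
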
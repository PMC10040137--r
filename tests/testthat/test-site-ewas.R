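# Site-level EWAS: design construction, likelihood-ratio and interaction
# tests against independent oracles, BH-FDR, and recovery on simulated
# cohorts.

ewasPairs <- function(n = 60, seed = 1) {
  set.seed(seed)
  data.frame(
    newborn_sex = sample(c("female", "male"), n, replace = TRUE),
    maternal_age = runif(n, 18, 42),
    race = sample(c("Black", "non-Black"), n, replace = TRUE),
    smoking = sample(c("no", "yes"), n, replace = TRUE),
    preterm = sample(c("no", "yes"), n, replace = TRUE),
    delivery = sample(c("vaginal", "C-section"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

test_that("the full design adds exactly the maternal main effect and its interactions", {
  pairs <- ewasPairs()
  set.seed(2)
  m <- rnorm(60)
  svs <- matrix(rnorm(60 * 4), 60, 4,
                dimnames = list(NULL, paste0("sv_", 1:4)))
  d <- buildDesigns(pairs, svs, m)
  # reduced: intercept + sex + 5 covariate columns + 4 SVs
  expect_equal(ncol(d$reduced), 2 + 5 + 4)
  # full adds maternal, maternal:sex, and 5 maternal:covariate columns
  expect_equal(ncol(d$full), ncol(d$reduced) + 7)
  expect_true(all(c("maternal", "maternal:sex") %in% colnames(d$full)))
  # SVs enter as main effects only: no maternal x SV columns
  expect_false(any(grepl("sv", setdiff(colnames(d$full),
                                       colnames(d$reduced))[-(1:2)])))

  d0 <- buildDesigns(pairs, NULL, m)
  expect_equal(ncol(d0$reduced), 7)
  expect_equal(ncol(d0$full), 14)

  pairs$smoking <- "no"   # single level
  expect_warning(d1 <- buildDesigns(pairs, NULL, m), "single level")
  expect_equal(ncol(d1$reduced), 6)
})

test_that("listwise deletion drops incomplete pairs and counts them", {
  pairs <- ewasPairs()
  pairs$maternal_age[c(3, 9)] <- NA
  m <- rnorm(60)
  d <- buildDesigns(pairs, NULL, m)
  expect_equal(d$nDropped, 2)
  expect_equal(nrow(d$full), 58)
})

test_that("the LRT statistic equals the Gaussian log-likelihood oracle", {
  pairs <- ewasPairs(n = 80, seed = 5)
  set.seed(6)
  m <- inverseNormalTransform(rnorm(80))
  y <- inverseNormalTransform(0.4 * m + rnorm(80))
  d <- buildDesigns(pairs, NULL, m)
  fit <- fitSite(y, d)
  # independent oracle: 2*(logLik_full - logLik_reduced) from lm()
  lf <- stats::logLik(lm(y ~ d$full - 1))
  lr <- stats::logLik(lm(y ~ d$reduced - 1))
  expect_lt(abs(fit$lrt_stat - 2 * (as.numeric(lf) - as.numeric(lr))), 1e-8)
  expect_equal(fit$p_lrt,
               pchisq(fit$lrt_stat, df = 7, lower.tail = FALSE))

  # Wald t p-value equals the single-constraint F-test p (model comparison)
  noInter <- d$full[, colnames(d$full) != "maternal:sex"]
  f1 <- lm(y ~ d$full - 1)
  f0 <- lm(y ~ noInter - 1)
  pF <- anova(f0, f1)$`Pr(>F)`[2]
  expect_lt(abs(fit$p_interaction - pF), 1e-10)

  # invariance to affine rescaling of covariate columns
  pairs2 <- pairs
  pairs2$maternal_age <- 3.7 * pairs$maternal_age - 12
  d2 <- buildDesigns(pairs2, NULL, m)
  fit2 <- fitSite(y, d2)
  expect_lt(abs(fit$lrt_stat - fit2$lrt_stat), 1e-8)
})

test_that("useless maternal terms give statistic zero and p one", {
  pairs <- ewasPairs(n = 50, seed = 8)
  set.seed(9)
  m <- rnorm(50)
  d <- buildDesigns(pairs, NULL, m)
  extras <- d$full[, setdiff(colnames(d$full), colnames(d$reduced))]
  # construct y whose residual on the reduced model is orthogonal to the
  # extra columns: then RSS_full = RSS_reduced exactly
  e <- qr.resid(qr(cbind(d$reduced, extras)), rnorm(50))
  y <- d$reduced %*% rnorm(ncol(d$reduced)) + e
  fit <- fitSite(as.numeric(y), d)
  expect_lt(abs(fit$lrt_stat), 1e-8)
  expect_gt(fit$p_lrt, 0.999)
})

test_that("BH q-values match the hand step-up and the brute-force oracle", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.37), 0.37)
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(bhFdr(numeric(0)), numeric(0))
  set.seed(10)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhFdr(p), bruteForceBH(p))
  }
  # q >= p elementwise
  p <- runif(200)
  expect_true(all(bhFdr(p) >= p))
})

test_that("the EWAS separates heritable from non-heritable sites", {
  cfg <- cohortConfig(nPairs = 200, nAutoSites = 600, nXSites = 20,
                      fracXInactivated = 0, h2Mixture = c(0.5, 0.05, 0.95),
                      nLatentFactors = 0L, seed = 22)
  mps <- simulateCohort(cfg)
  res <- runSiteEwas(mps)
  h2 <- siteAnno(mps)$h2
  expect_lt(median(res$p_lrt[h2 >= 0.6]), median(res$p_lrt[h2 <= 0.05]))
  # heritability enrichment direction among significant sites
  expect_gt(mean(h2[res$significant_lrt]), mean(h2))
})

test_that("injected maternal-by-sex interactions are recovered", {
  cfg <- nullConfig(nPairs = 400L, nAutoSites = 500L, nXSites = 40L,
                    seed = 30L)
  mps <- simulateCohort(cfg)
  lm_ <- stats::qlogis(maternalBeta(mps))
  lc <- stats::qlogis(neonatalBeta(mps))
  fem <- newbornSex(mps) == "female"
  for (j in 1:20) lc[j, fem] <- lc[j, fem] + 0.5 * lm_[j, fem]
  mps2 <- MethylPairSet(stats::plogis(lm_), stats::plogis(lc),
                        as.data.frame(pairData(mps)), siteAnno(mps))
  res <- runSiteEwas(mps2)
  expect_gte(sum(res$fdr_interaction[1:20] < 0.1), 15)
})

test_that("degenerate sites are flagged rather than fatal", {
  set.seed(33)
  M <- matrix(runif(40 * 5), 5, 40)
  C <- matrix(runif(40 * 5), 5, 40)
  M[1, ] <- 0.5   # constant maternal vector: INT fails
  mps <- makePairSet(M, C)
  res <- runSiteEwas(mps)
  expect_equal(res$flag[1], "degenerate_site")
  expect_true(is.na(res$p_lrt[1]))
  expect_false(any(is.na(res$p_lrt[-1])))
})
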
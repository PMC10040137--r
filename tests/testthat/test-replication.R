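# Two-cohort replication: overlap, direction concordance, and printed
# proportion arithmetic.

fakeResults <- function(ids, beta, p, chrom = "1") {
  out <- data.frame(site_id = ids, chromosome = chrom, beta_sex = beta,
                    p = p, fdr = bhFdr(p), stringsAsFactors = FALSE)
  attr(out, "sex_coding") <- "0 = female, 1 = male"
  out
}

test_that("overlap joins discovery-significant sites onto replication results", {
  set.seed(1)
  ids <- sprintf("cg%05d", 1:100)
  disc <- fakeResults(ids, rnorm(100), c(rep(1e-6, 30), runif(70, 0.2, 1)))
  repl <- fakeResults(ids[1:50], rnorm(50), runif(50))
  joined <- overlapResults(disc, repl)
  # brute-force set oracle
  sigIds <- disc$site_id[disc$fdr < 0.05]
  expect_setequal(joined$site_id, intersect(sigIds, repl$site_id))

  expect_error(overlapResults(disc, fakeResults("cgX", 1, 0.5)),
               "no overlap")
  # identical tables: overlap equals the discovery-significant count
  joined2 <- overlapResults(disc, disc)
  expect_equal(nrow(joined2), sum(disc$fdr < 0.05))
  # mismatched sex coding refuses to join
  repl2 <- repl
  attr(repl2, "sex_coding") <- "0 = male, 1 = female"
  expect_error(overlapResults(disc, repl2), "sex coding")
})

test_that("concordance reproduces printed percentages and the 50:50 chi-square", {
  # 8,896 overlapping sites; 1,245 replication-significant, 1,114 consistent
  n <- 8896
  nSig <- 1245
  nCons <- 1114
  beta1 <- c(rep(1, nCons), rep(1, nSig - nCons), rep(1, n - nSig))
  beta2 <- c(rep(1, nCons), rep(-1, nSig - nCons), rnorm(n - nSig))
  p <- c(rep(1e-12, nSig), runif(n - nSig, 0.5, 1))
  joined <- data.frame(site_id = sprintf("cg%07d", 1:n),
                       beta_sex.disc = beta1, beta_sex.repl = beta2,
                       p.repl = p)
  cs <- concordanceSummary(joined)
  expect_equal(cs$n_sig_replication, nSig)
  expect_equal(cs$n_consistent_direction, nCons)
  expect_equal(cs$pct_consistent, 89.5)
  expect_equal(cs$chisq_stat, (2 * nCons - nSig)^2 / nSig)
  expect_equal(cs$p, pchisq(cs$chisq_stat, 1, lower.tail = FALSE))

  # 1,827 significant of which 1,664 consistent -> 91.1%
  expect_equal(proportionSignificant(1664, 1827), 91.1)

  # all consistent (k of k): pct 100 and statistic k
  k <- 37
  joinedK <- data.frame(site_id = sprintf("s%d", 1:k),
                        beta_sex.disc = rep(c(1, -1), length.out = k),
                        beta_sex.repl = rep(c(2, -3), length.out = k),
                        p.repl = rep(1e-8, k))
  csK <- concordanceSummary(joinedK)
  expect_equal(csK$pct_consistent, 100)
  expect_equal(csK$chisq_stat, k)

  # zero replication-significant sites: missing summary, not an error
  joined0 <- joined
  joined0$p.repl <- runif(n, 0.5, 1)
  cs0 <- concordanceSummary(joined0)
  expect_true(is.na(cs0$pct_consistent) && is.na(cs0$p))
})

test_that("chi-square concordance p decreases as the split departs from 50:50", {
  n <- 400
  ps <- sapply(c(210, 250, 300, 380), function(k) {
    stat <- (2 * k - n)^2 / n
    pchisq(stat, 1, lower.tail = FALSE)
  })
  expect_true(all(diff(ps) < 0))
})

test_that("proportion arithmetic matches printed cohort values", {
  expect_equal(proportionSignificant(88051, 704552), 12.5)
  expect_equal(proportionSignificant(1216, 16779), 7.2)
  expect_equal(proportionSignificant(89267, 721331), 12.4)
  expect_equal(proportionSignificant(14482, 16779), 86.3)
  expect_equal(proportionSignificant(8572, 15871), 54.0)
  expect_equal(proportionSignificant(0, 10), 0)
  expect_error(proportionSignificant(1, 0), "positive")
  expect_error(proportionSignificant(-1, 10), "nSignificant")
})

test_that("half-cohorts simulated from one truth replicate each other's directions", {
  consistent <- numeric(3)
  for (i in 1:3) {
    cfg <- cohortConfig(nPairs = 300, nAutoSites = 600, nXSites = 300,
                        seed = 90L + i)
    mps <- simulateCohort(cfg)
    half1 <- seq(1, ncol(mps), by = 2)
    half2 <- seq(2, ncol(mps), by = 2)
    runHalf <- function(idx) {
      sub <- mps[, idx]
      runDeltaEwas(computeDelta(sub), as.data.frame(pairData(sub)),
                   chromosome = siteAnno(sub)$chromosome)
    }
    r1 <- runHalf(half1)
    r2 <- runHalf(half2)
    joined <- overlapResults(r1, r2)
    cs <- concordanceSummary(joined)
    consistent[i] <- cs$pct_consistent
  }
  expect_true(all(consistent > 75))
})
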
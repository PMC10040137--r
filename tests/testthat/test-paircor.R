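# Per-pair Spearman correlations, the sex-matched derangement background,
# and the t comparisons.

test_that("pair Spearman matches the closed-form rank formula and its bounds", {
  # 5-point example: neonatal ranks (1,3,2,5,4), sum d^2 = 4,
  # rho = 1 - 6*4/(5*24) = 0.8
  m <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5), ncol = 1)
  c1 <- matrix(c(0.1, 0.3, 0.2, 0.5, 0.4), ncol = 1)
  mps <- makePairSet(cbind(m, m), cbind(c1, m), sex = c("female", "male"))
  pc <- pairSpearman(mps)
  expect_equal(pc$rho_all[1], 1 - 6 * 4 / (5 * (25 - 1)))
  expect_equal(pc$rho_auto[1], pc$rho_all[1])   # all sites autosomal
  expect_equal(pc$rho_all[2], 1)                # identity pair
  # rank reversal
  mps2 <- makePairSet(cbind(m), 1 - cbind(m), sex = "female")
  expect_equal(pairSpearman(mps2)$rho_all, -1)
  # NA handling drops site pairs
  mna <- cbind(c(m[1:4], NA))
  mpsNA <- makePairSet(mna, c1, sex = "male")
  expect_equal(pairSpearman(mpsNA)$rho_all,
               cor(m[1:4], c1[1:4], method = "spearman"))
})

test_that("X and autosomal subsets are computed over the annotated sites", {
  set.seed(8)
  M <- matrix(runif(40), 20, 2)
  C <- matrix(runif(40), 20, 2)
  chrom <- rep(c("1", "X"), each = 10)
  mps <- makePairSet(M, C, chromosome = chrom)
  pc <- pairSpearman(mps)
  expect_equal(pc$rho_auto[1],
               cor(M[1:10, 1], C[1:10, 1], method = "spearman"))
  expect_equal(pc$rho_x[1],
               cor(M[11:20, 1], C[11:20, 1], method = "spearman"))
})

test_that("derangements never keep a fixed point and strata of 1 fail", {
  set.seed(5)
  for (k in c(2, 3, 5, 12)) {
    for (i in 1:25) {
      p <- duomethyl:::.derangement(k)
      expect_false(any(p == seq_len(k)))
      expect_setequal(p, seq_len(k))
    }
  }
  expect_error(duomethyl:::.derangement(1), "derangement")
})

test_that("the permutation background is seeded, sex-matched and forced for 2 pairs", {
  # two male pairs: the only derangement is the swap
  set.seed(2)
  M <- matrix(runif(60), 30, 2)
  C <- matrix(runif(60), 30, 2)
  mps <- makePairSet(M, C, sex = c("male", "male"))
  bg <- permutationBackground(mps, nIter = 3, seed = 11)
  expect_equal(bg$rho_all[1], cor(M[, 2], C[, 1], method = "spearman"))
  expect_equal(bg$rho_all[2], cor(M[, 1], C[, 2], method = "spearman"))

  cfg <- nullConfig(nPairs = 40L, nAutoSites = 200L, seed = 3L)
  mps2 <- simulateCohort(cfg)
  b1 <- permutationBackground(mps2, nIter = 4, seed = 21)
  b2 <- permutationBackground(mps2, nIter = 4, seed = 21)
  expect_identical(b1, b2)
  b3 <- permutationBackground(mps2, nIter = 4, seed = 22)
  expect_false(identical(b1$rho_all, b3$rho_all))

  expect_error(permutationBackground(mps2, nIter = 0), "nIter")
  mps1 <- makePairSet(M, C, sex = c("male", "female"))
  expect_error(permutationBackground(mps1), "stratum")
})

test_that("without family signal the background matches the matched distribution", {
  mps <- simulateCohort(nullConfig(nPairs = 100L, nAutoSites = 600L,
                                   nXSites = 30L, seed = 61))
  pc <- pairSpearman(mps)
  bg <- permutationBackground(mps, nIter = 10, seed = 62)
  cmp <- compareMatchedVsBackground(pc, bg, "all")
  expect_gt(cmp$p, 0.05)
  expect_lt(abs(cmp$group_means["matched"] - cmp$group_means["background"]),
            0.01)
})

test_that("matched exceeds background when heritability is substantial", {
  cfg <- cohortConfig(nPairs = 200, nAutoSites = 2000, nXSites = 500,
                      h2Mixture = c(0, 0.4, 0.4), seed = 46)
  mps <- simulateCohort(cfg)
  pc <- pairSpearman(mps)
  bg <- permutationBackground(mps, nIter = 10, seed = 7)
  cmp <- compareMatchedVsBackground(pc, bg, "all")
  expect_gt(cmp$group_means["matched"], cmp$group_means["background"])
  expect_lt(cmp$p, 0.01)
})

test_that("paired t behaves under degeneracy and uniform shifts", {
  set.seed(9)
  matched <- data.frame(pair_id = sprintf("P%02d", 1:30),
                        newborn_sex = "female",
                        rho_all = runif(30, 0.8, 0.95))
  bg <- matched
  bg$source <- "background"
  cmp <- compareMatchedVsBackground(matched, bg, "all")
  expect_equal(cmp$p, 1)
  expect_true("degenerate_variance" %in% cmp$flags)

  bg2 <- matched
  bg2$rho_all <- matched$rho_all - runif(30, 0, 0.1)
  t0 <- compareMatchedVsBackground(matched, bg2, "all")
  # shifting the background by +c shifts the statistic by -c*sqrt(n)/sd(d)
  cshift <- 0.03
  bg3 <- bg2
  bg3$rho_all <- bg2$rho_all + cshift
  t1 <- compareMatchedVsBackground(matched, bg3, "all")
  d <- matched$rho_all - bg2$rho_all
  expect_equal(t1$statistic,
               t0$statistic - cshift * sqrt(30) / sd(d), tolerance = 1e-10)
})

test_that("between-sex comparison is Welch and requires both sexes", {
  rho <- c(0.9, 0.91, 0.92, 0.9, 0.91, 0.92)
  matched <- data.frame(pair_id = sprintf("P%02d", 1:6),
                        newborn_sex = rep(c("female", "male"), each = 3),
                        rho_x = rho)
  cmp <- compareBySex(matched, "x")
  expect_equal(unname(cmp$group_means["female"] - cmp$group_means["male"]), 0)
  expect_gt(cmp$p, 0.99)
  expect_error(compareBySex(matched[1:3, ], "x"), "both")
})

test_that("under the X-inactivation model mother-female X correlations exceed mother-male", {
  cfg <- cohortConfig(nPairs = 200, nAutoSites = 800, nXSites = 400,
                      seed = 11)
  mps <- simulateCohort(cfg)
  pc <- pairSpearman(mps)
  cmp <- compareBySex(pc, "x")
  expect_gt(cmp$group_means["female"], cmp$group_means["male"])
  expect_lt(cmp$p, 0.01)
  # weak mixture sanity: rho_all lies near the site-weighted mix of subsets
  w <- 800 / 1200
  blend <- w * pc$rho_auto + (1 - w) * pc$rho_x
  expect_true(all(abs(pc$rho_all - blend) < 0.1))
})
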
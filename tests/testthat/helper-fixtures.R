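# Shared fixtures: small cohort configurations and hand-built pair sets.

# all-null cohort: no heritability, no sex effects, no latent structure,
# X sites behave autosomally (no inactivation)
nullConfig <- function(nPairs = 100L, nAutoSites = 400L, nXSites = 20L,
                       seed = 1L, ...) {
  cohortConfig(nPairs = nPairs, nAutoSites = nAutoSites, nXSites = nXSites,
               fracXInactivated = 0, h2Mixture = c(0, 0, 0),
               fracSexDifferential = 0, nLatentFactors = 0L,
               ageSlopeSD = 0, seed = seed, ...)
}

# build a MethylPairSet directly from beta matrices and a minimal sheet
makePairSet <- function(maternal, neonatal, sex = NULL, chromosome = NULL) {
  n <- ncol(maternal)
  if (is.null(sex)) sex <- rep(c("female", "male"), length.out = n)
  if (is.null(chromosome)) chromosome <- rep("1", nrow(maternal))
  ids <- sprintf("P%03d", seq_len(n))
  sites <- if (is.null(rownames(maternal)))
    sprintf("cg%05d", seq_len(nrow(maternal))) else rownames(maternal)
  dimnames(maternal) <- dimnames(neonatal) <- list(sites, ids)
  # covariate cycles use coprime periods so no two columns are collinear
  pairs <- data.frame(pair_id = ids, newborn_sex = sex,
                      maternal_age = seq(20, 40, length.out = n),
                      race = rep(c("Black", "Black", "non-Black",
                                   "non-Black", "Black"), length.out = n),
                      smoking = rep(c("no", "no", "yes"), length.out = n),
                      preterm = rep(c("no", "no", "no", "yes"), length.out = n),
                      delivery = rep(c("vaginal", "C-section", "vaginal",
                                       "vaginal", "C-section", "vaginal",
                                       "C-section"), length.out = n),
                      row.names = ids, stringsAsFactors = FALSE)
  anno <- S4Vectors::DataFrame(site_id = sites, chromosome = chromosome,
                               row.names = sites)
  MethylPairSet(maternal, neonatal, pairs, anno)
}

# brute-force BH step-up used as the independent oracle
bruteForceBH <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- rep(NA_real_, n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[ord[i]] * n / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}

# exact hypergeometric upper-tail by enumeration over overlap values
bruteForceHyper <- function(k, K, N, q) {
  kmax <- min(K, q)
  sum(vapply(k:kmax, function(i)
    choose(K, i) * choose(N - K, q - i), numeric(1))) / choose(N, q)
}
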
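# Synthetic mother-newborn methylome generator.
#
# Generative contract, per site j and pair i, on the logit scale:
#   logit(beta_maternal) = mu_j + ageSlope_j*(age_i - midAge)
#                          + g_m + sum_k loading_jk * L_ik + e,
# with Var(g_m) = h2_j * noiseSD^2 and Var(e) = (1 - h2_j) * noiseSD^2.
# The newborn genetic value is g_c = 0.5*g_m + r with Var(r) =
# 0.75*Var(g_m) (additive model; mother-child genetic correlation 0.5,
# hence a logit-scale mother-child correlation of h2/2 in the absence of
# shared latent structure). Male newborns add sex_effect_j at flagged
# autosomal sites. X-inactivated sites emit, for mothers and female
# newborns, the equal-weight allele average
#   0.5 * (invlogit(active draw) + invlogit(inactive draw)),
# where the inactive-allele mean sits muInactiveOffset above the active
# mean (the inactive X is predominantly methylated); male newborns emit
# the single active-allele draw.

.siteCategories <- list(
  functional_region = c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                        "3'UTR", "intergenic"),
  island_relation = c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                      "OpenSea")
)

# internal: draws everything after the caller has fixed the RNG state
.simulateSiteParams <- function(config) {
  mA <- config@nAutoSites
  mX <- config@nXSites
  m <- mA + mX
  K <- config@nLatentFactors

  chromClass <- rep("autosome", m)
  nInact <- round(config@fracXInactivated * mX)
  xClass <- rep("X_escape", mX)
  if (nInact > 0) xClass[sample.int(mX, nInact)] <- "X_inactivated"
  chromClass[(mA + 1):m] <- xClass
  inact <- chromClass == "X_inactivated"

  siteId <- sprintf("cg%07d", seq_len(m))
  chromosome <- c(as.character(sample.int(22L, mA, replace = TRUE)),
                  rep("X", mX))
  position <- sample.int(150000000L, m, replace = TRUE)

  # gene assignment: ~10% intergenic, ~5% annotated to two genes
  genePool <- sprintf("GENE%04d", seq_len(max(2L, ceiling(m / 3))))
  gene <- sample(genePool, m, replace = TRUE)
  second <- sample(genePool, m, replace = TRUE)
  two <- stats::runif(m) < 0.05 & second != gene
  gene[two] <- paste(gene[two], second[two], sep = ";")
  intergenic <- stats::runif(m) < 0.10 & !inact
  gene[intergenic] <- ""

  fr <- sample(.siteCategories$functional_region[1:6], m, replace = TRUE,
               prob = c(0.16, 0.12, 0.14, 0.08, 0.42, 0.08))
  fr[intergenic] <- "intergenic"
  # inactivated X sites skew promoter/island-like
  fr[inact] <- sample(.siteCategories$functional_region[1:6], sum(inact),
                      replace = TRUE,
                      prob = c(0.3, 0.2, 0.15, 0.1, 0.2, 0.05))
  ir <- sample(.siteCategories$island_relation, m, replace = TRUE,
               prob = c(0.31, 0.12, 0.10, 0.05, 0.05, 0.37))
  ir[inact] <- sample(.siteCategories$island_relation, sum(inact),
                      replace = TRUE,
                      prob = c(0.7, 0.12, 0.10, 0.02, 0.02, 0.04))

  # baseline means: bimodal for ordinary sites, promoter-island-like (low)
  # for inactivated X sites
  comp <- sample.int(3L, m, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  mu <- c(-2.5, 2.5, 0)[comp] + stats::rnorm(m, 0, c(0.7, 0.7, 1)[comp])
  mu[inact] <- stats::rnorm(sum(inact), -2.5, 0.7)

  fracLow <- config@h2Mixture[1]
  lowMax <- config@h2Mixture[2]
  highMax <- config@h2Mixture[3]
  low <- stats::runif(m) < fracLow
  h2 <- ifelse(low, stats::runif(m, 0, lowMax),
               stats::runif(m, lowMax, highMax))

  sexEffect <- numeric(m)
  autoIdx <- which(chromClass == "autosome")
  nSexDiff <- round(config@fracSexDifferential * length(autoIdx))
  if (nSexDiff > 0) {
    flagged <- sample(autoIdx, nSexDiff)
    sexEffect[flagged] <- stats::rnorm(nSexDiff, 0, config@sexEffectSD)
  }

  ageSlope <- stats::rnorm(m, 0, config@ageSlopeSD)

  muInactive <- rep(NA_real_, m)
  muInactive[inact] <- mu[inact] +
    stats::rnorm(sum(inact), config@muInactiveOffset[1],
                 config@muInactiveOffset[2])

  out <- data.frame(
    site_id = siteId, chrom_class = chromClass, chromosome = chromosome,
    position = position, gene = gene, functional_region = fr,
    island_relation = ir, mu = mu, h2 = h2, sex_effect = sexEffect,
    age_slope = ageSlope, mu_inactive = muInactive,
    stringsAsFactors = FALSE)
  if (K > 0) {
    loadings <- matrix(stats::rnorm(m * K, 0, config@loadingSD), m, K,
                       dimnames = list(NULL, sprintf("loading_%d", seq_len(K))))
    out <- cbind(out, as.data.frame(loadings))
  }
  out
}

#' Draw per-site generator parameters
#'
#' Deterministic given \code{config@seed}; the same parameters open a
#' \code{\link{simulateCohort}} run with the same config.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return data.frame with one row per site: identifiers, chromosome class
#'   (\code{autosome}, \code{X_escape}, \code{X_inactivated}), manifest-style
#'   annotation columns, and the generative parameters \code{mu},
#'   \code{h2}, \code{sex_effect}, \code{age_slope}, \code{mu_inactive}
#'   and latent-factor loadings.
#' @export
#' @examples
#' head(simulateSiteParams(cohortConfig(nAutoSites = 20, nXSites = 5)))
simulateSiteParams <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  withSeed(config@seed, .simulateSiteParams(config))
}

#' Simulate a paired mother-newborn methylation cohort
#'
#' Generates matched maternal and neonatal beta-value matrices under an
#' additive genetic model with latent batch/cell-composition factors and an
#' X-inactivation allele-average model (see the package vignette for the
#' full generative contract). Betas are clipped strictly inside (0,1).
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return a \linkS4class{MethylPairSet}; \code{metadata(x)$truth} holds
#'   the truth table (site parameters, latent factor scores, and genetic
#'   values).
#' @export
#' @examples
#' mps <- simulateCohort(cohortConfig(nPairs = 30, nAutoSites = 100,
#'                                    nXSites = 40, seed = 3))
#' mps
simulateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  withSeed(config@seed, {
    params <- .simulateSiteParams(config)
    m <- nrow(params)
    n <- config@nPairs
    K <- config@nLatentFactors
    s <- config@noiseSD

    # pair sheet emulating an urban birth-cohort sample sheet
    nMale <- round(0.545 * n)
    sex <- sample(c(rep("male", nMale), rep("female", n - nMale)))
    midAge <- mean(config@maternalAgeRange)
    age <- stats::runif(n, config@maternalAgeRange[1],
                        config@maternalAgeRange[2])
    race <- ifelse(stats::runif(n) < 0.655, "Black", "non-Black")
    smoking <- ifelse(stats::runif(n) < 0.11, "yes", "no")
    pretermP <- ifelse(sex == "male", 0.208, 0.111)
    preterm <- ifelse(stats::runif(n) < pretermP, "yes", "no")
    delivery <- ifelse(stats::runif(n) < 0.306, "C-section", "vaginal")
    parity <- sample(c("1", "2", "3+"), n, replace = TRUE,
                     prob = c(0.46, 0.26, 0.28))
    pairId <- sprintf("P%04d", seq_len(n))
    pairs <- data.frame(
      pair_id = pairId,
      mother_sample_id = sprintf("M%04d", seq_len(n)),
      newborn_sample_id = sprintf("C%04d", seq_len(n)),
      newborn_sex = sex, maternal_age = age, race = race,
      smoking = smoking, preterm = preterm, delivery = delivery,
      parity = parity, row.names = pairId, stringsAsFactors = FALSE)

    Lm <- matrix(stats::rnorm(n * K), n, K)
    Lc <- if (config@sharedLatentScores) Lm else matrix(stats::rnorm(n * K), n, K)

    h2 <- params$h2
    gSd <- sqrt(h2) * s
    eSd <- sqrt(1 - h2) * s
    gM <- matrix(stats::rnorm(m * n), m, n) * gSd
    gC <- 0.5 * gM + matrix(stats::rnorm(m * n), m, n) * sqrt(0.75) * gSd
    eM <- matrix(stats::rnorm(m * n), m, n) * eSd
    eC <- matrix(stats::rnorm(m * n), m, n) * eSd

    load <- if (K > 0) as.matrix(params[, sprintf("loading_%d", seq_len(K)),
                                        drop = FALSE])
            else matrix(0, m, 0)
    male <- as.numeric(sex == "male")

    zM <- params$mu + outer(params$age_slope, age - midAge) + gM + eM
    zC <- params$mu + outer(params$sex_effect, male) + gC + eC
    if (K > 0) {
      zM <- zM + load %*% t(Lm)
      zC <- zC + load %*% t(Lc)
    }

    betaM <- stats::plogis(zM)
    betaC <- stats::plogis(zC)

    inact <- which(params$chrom_class == "X_inactivated")
    if (length(inact)) {
      mi <- length(inact)
      zInM <- params$mu_inactive[inact] + matrix(stats::rnorm(mi * n), mi, n) * s
      zInC <- params$mu_inactive[inact] + matrix(stats::rnorm(mi * n), mi, n) * s
      betaM[inact, ] <- 0.5 * (stats::plogis(zM[inact, , drop = FALSE]) +
                               stats::plogis(zInM))
      fem <- 0.5 * (stats::plogis(zC[inact, , drop = FALSE]) +
                    stats::plogis(zInC))
      mal <- stats::plogis(zC[inact, , drop = FALSE])
      isMale <- matrix(male == 1, mi, n, byrow = TRUE)
      betaC[inact, ] <- ifelse(isMale, mal, fem)
    }

    betaM <- clipBeta(betaM)
    betaC <- clipBeta(betaC)
    dimnames(betaM) <- dimnames(betaC) <- list(params$site_id, pairId)

    anno <- S4Vectors::DataFrame(
      params[, c("site_id", "chrom_class", "chromosome", "position", "gene",
                 "functional_region", "island_relation", "h2")],
      row.names = params$site_id)

    truth <- list(siteParams = params,
                  latentMaternal = Lm, latentNeonatal = Lc,
                  geneticMaternal = gM, geneticNeonatal = gC)
    MethylPairSet(betaM, betaC, pairs, anno,
                  metadata = list(truth = truth, seed = config@seed))
  })
}
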
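#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' CohortConfig: parameters of the synthetic paired-methylome generator
#'
#' Holds every tunable of the mother-newborn cohort simulator. Methylation
#' is generated on the logit scale and mapped to beta values by the inverse
#' logit, so heritability (\code{h2}) is interpretable as a variance
#' fraction on the modelling scale. The per-site total biological SD on the
#' logit scale is \code{noiseSD}; a site with heritability h2 splits it
#' into a genetic SD \code{sqrt(h2)*noiseSD} and an environmental SD
#' \code{sqrt(1-h2)*noiseSD}. The newborn genetic value is
#' \code{0.5*maternal + independent remainder}, giving the canonical
#' parent-offspring correlation of h2/2 on the logit scale.
#'
#' @slot nPairs number of mother-newborn pairs.
#' @slot nAutoSites,nXSites numbers of autosomal and X-chromosomal sites.
#' @slot fracXInactivated fraction of X sites subject to X-inactivation
#'   (the remainder escape and behave like autosomal sites).
#' @slot h2Mixture length-3 numeric \code{c(fracLow, lowMax, highMax)}:
#'   a fraction \code{fracLow} of sites draw h2 from Uniform(0, lowMax)
#'   (near-null mass) and the rest from Uniform(lowMax, highMax).
#' @slot fracSexDifferential fraction of autosomal sites given a nonzero
#'   additive logit-scale sex effect in newborns.
#' @slot sexEffectSD SD of the sex effect at flagged sites (logit units).
#' @slot nLatentFactors number of latent batch/cell-composition factors.
#' @slot loadingSD SD of per-site latent-factor loadings (logit units).
#' @slot sharedLatentScores if TRUE, mother and newborn of a pair share
#'   latent factor scores (mimics batch co-placement); default FALSE,
#'   independent scores.
#' @slot noiseSD total per-site biological SD on the logit scale.
#' @slot maternalAgeRange length-2 range of maternal age at delivery
#'   (years), sampled uniformly.
#' @slot ageSlopeSD SD of the per-site maternal age drift (logit units per
#'   year, applied to mothers around the mid-range age).
#' @slot muInactiveOffset length-2 \code{c(mean, sd)} of the logit-scale
#'   offset of the inactive-X allele mean above the active-allele mean
#'   (the inactive X is predominantly methylated at island promoters).
#' @slot seed integer RNG seed.
#' @export
setClass("CohortConfig",
  representation(
    nPairs = "integer",
    nAutoSites = "integer",
    nXSites = "integer",
    fracXInactivated = "numeric",
    h2Mixture = "numeric",
    fracSexDifferential = "numeric",
    sexEffectSD = "numeric",
    nLatentFactors = "integer",
    loadingSD = "numeric",
    sharedLatentScores = "logical",
    noiseSD = "numeric",
    maternalAgeRange = "numeric",
    ageSlopeSD = "numeric",
    muInactiveOffset = "numeric",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  chkCount <- function(x, nm, min = 1L) {
    if (length(x) != 1 || is.na(x) || x < min)
      sprintf("'%s' must be a single count >= %d", nm, min)
    else character()
  }
  chkFrac <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x < 0 || x > 1)
      sprintf("'%s' must be a fraction in [0,1]", nm)
    else character()
  }
  msg <- c(msg,
    chkCount(object@nPairs, "nPairs"),
    chkCount(object@nAutoSites, "nAutoSites"),
    chkCount(object@nXSites, "nXSites"),
    chkCount(object@nLatentFactors, "nLatentFactors", min = 0L),
    chkFrac(object@fracXInactivated, "fracXInactivated"),
    chkFrac(object@fracSexDifferential, "fracSexDifferential"))
  if (length(object@h2Mixture) != 3 || any(is.na(object@h2Mixture)) ||
      object@h2Mixture[1] < 0 || object@h2Mixture[1] > 1 ||
      object@h2Mixture[2] < 0 || object@h2Mixture[3] > 1 ||
      object@h2Mixture[2] > object@h2Mixture[3])
    msg <- c(msg, "'h2Mixture' must be c(fracLow, lowMax, highMax) with 0 <= lowMax <= highMax <= 1")
  if (length(object@noiseSD) != 1 || is.na(object@noiseSD) || object@noiseSD <= 0)
    msg <- c(msg, "'noiseSD' must be a single positive number")
  if (length(object@maternalAgeRange) != 2 ||
      any(is.na(object@maternalAgeRange)) ||
      diff(object@maternalAgeRange) < 0)
    msg <- c(msg, "'maternalAgeRange' must be a nondecreasing length-2 range")
  if (length(object@muInactiveOffset) != 2 || object@muInactiveOffset[2] < 0)
    msg <- c(msg, "'muInactiveOffset' must be c(mean, sd) with sd >= 0")
  if (object@sexEffectSD < 0 || object@loadingSD < 0 || object@ageSlopeSD < 0)
    msg <- c(msg, "'sexEffectSD', 'loadingSD' and 'ageSlopeSD' must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortConfig
#'
#' All arguments have defaults emulating a moderately sized birth-cohort
#' design: a few hundred pairs, a few thousand sites with a long-right-tail
#' heritability distribution, most X sites subject to X-inactivation, a
#' small minority of autosomal sites sex-differential, and a handful of
#' latent batch/cell-composition factors.
#'
#' @param nPairs,nAutoSites,nXSites cohort and panel sizes.
#' @param fracXInactivated fraction of X sites under X-inactivation.
#' @param h2Mixture \code{c(fracLow, lowMax, highMax)} heritability mixture.
#' @param fracSexDifferential fraction of sex-differential autosomal sites.
#' @param sexEffectSD SD of the newborn sex effect at flagged sites (logit).
#' @param nLatentFactors,loadingSD,sharedLatentScores latent factor model.
#' @param noiseSD total per-site biological SD on the logit scale.
#' @param maternalAgeRange maternal age range in years.
#' @param ageSlopeSD SD of per-site maternal age drift (logit/year).
#' @param muInactiveOffset \code{c(mean, sd)} of the inactive-allele offset.
#' @param seed integer RNG seed.
#' @return a validated \linkS4class{CohortConfig}.
#' @export
#' @examples
#' cfg <- cohortConfig(nPairs = 50, nAutoSites = 200, nXSites = 50, seed = 7)
cohortConfig <- function(nPairs = 200L, nAutoSites = 4000L, nXSites = 1000L,
                         fracXInactivated = 0.75,
                         h2Mixture = c(0.6, 0.05, 0.95),
                         fracSexDifferential = 0.05,
                         sexEffectSD = 0.3,
                         nLatentFactors = 3L, loadingSD = 0.3,
                         sharedLatentScores = FALSE,
                         noiseSD = 0.5,
                         maternalAgeRange = c(15, 46),
                         ageSlopeSD = 0.005,
                         muInactiveOffset = c(3, 0.5),
                         seed = 1L) {
  obj <- try(new("CohortConfig",
    nPairs = as.integer(nPairs), nAutoSites = as.integer(nAutoSites),
    nXSites = as.integer(nXSites), fracXInactivated = fracXInactivated,
    h2Mixture = h2Mixture, fracSexDifferential = fracSexDifferential,
    sexEffectSD = sexEffectSD, nLatentFactors = as.integer(nLatentFactors),
    loadingSD = loadingSD, sharedLatentScores = sharedLatentScores,
    noiseSD = noiseSD, maternalAgeRange = as.numeric(maternalAgeRange),
    ageSlopeSD = ageSlopeSD, muInactiveOffset = as.numeric(muInactiveOffset),
    seed = as.integer(seed)), silent = TRUE)
  if (inherits(obj, "try-error"))
    stop("invalid cohort configuration: ", attr(obj, "condition")$message,
         call. = FALSE)
  obj
}

#' MethylPairSet: paired maternal/neonatal beta values
#'
#' A \linkS4class{SummarizedExperiment} with two assays, \code{maternal}
#' and \code{neonatal}, holding beta values (sites x pairs, each column a
#' mother-newborn pair). \code{colData} carries the pair sheet (newborn
#' sex and clinical covariates); \code{rowData} carries the site
#' annotation (chromosome, position, gene, functional region, island
#' relation, optional heritability). For simulated cohorts,
#' \code{metadata(x)$truth} carries the generator truth table.
#'
#' @export
setClass("MethylPairSet", contains = "SummarizedExperiment")

setValidity("MethylPairSet", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("maternal", "neonatal") %in% an))
    return("assays 'maternal' and 'neonatal' are required")
  for (a in c("maternal", "neonatal")) {
    v <- SummarizedExperiment::assay(object, a)
    bad <- v[!is.na(v)]
    if (length(bad) && (min(bad) < 0 || max(bad) > 1))
      msg <- c(msg, sprintf("assay '%s' has beta values outside [0,1]", a))
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"newborn_sex" %in% colnames(cd))
    msg <- c(msg, "colData must contain 'newborn_sex'")
  else if (!all(cd$newborn_sex %in% c("female", "male")))
    msg <- c(msg, "'newborn_sex' must be 'female' or 'male'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate site identifiers")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate pair identifiers")
  if (length(msg)) msg else TRUE
})

#' Construct a MethylPairSet
#'
#' @param maternal,neonatal numeric matrices of beta values (sites x
#'   pairs) with identical dimnames; rows are sites, columns pairs.
#' @param pairData a data.frame or DataFrame of per-pair covariates,
#'   one row per column of the matrices; must include \code{newborn_sex}.
#' @param siteAnnotation a data.frame or DataFrame of per-site annotation,
#'   one row per matrix row; should include \code{chromosome}.
#' @param metadata optional list stored as object metadata.
#' @return a \linkS4class{MethylPairSet}.
#' @export
MethylPairSet <- function(maternal, neonatal, pairData, siteAnnotation = NULL,
                          metadata = list()) {
  stopifnot(is.matrix(maternal), is.matrix(neonatal),
            all(dim(maternal) == dim(neonatal)))
  if (!identical(dimnames(maternal), dimnames(neonatal)))
    stop("'maternal' and 'neonatal' must share dimnames", call. = FALSE)
  if (is.null(siteAnnotation))
    siteAnnotation <- S4Vectors::DataFrame(row.names = rownames(maternal))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(maternal = maternal, neonatal = neonatal),
    colData = S4Vectors::DataFrame(pairData),
    rowData = siteAnnotation,
    metadata = metadata)
  new("MethylPairSet", se)
}
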
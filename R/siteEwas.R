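# Per-site full/reduced regression of neonatal on maternal methylation
# with likelihood-ratio testing and the maternal x sex interaction Wald
# test.
#
# Both methylation vectors are inverse-normal-transformed per site. The
# reduced model is neonatal ~ sex + covariates + SVs; the full model adds
# the maternal main effect, maternal x sex, and maternal x each clinical
# covariate (SVs enter as main effects only). The LRT statistic is the
# Gaussian profile form n*log(RSS_reduced/RSS_full), referred to a
# chi-square with df equal to the column-count difference.

.defaultCovariates <- c("maternal_age", "race", "smoking", "preterm",
                        "delivery")

# covariate model matrix (no intercept column), dropping single-level
# covariates with a warning; factors enter as treatment contrasts
.covariateMatrix <- function(pairs, covariates) {
  cols <- list()
  for (cv in covariates) {
    v <- pairs[[cv]]
    if (is.null(v))
      stop("covariate '", cv, "' missing from pair table", call. = FALSE)
    if (is.numeric(v)) {
      cols[[cv]] <- matrix(v, ncol = 1, dimnames = list(NULL, cv))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) {
        warning("covariate '", cv, "' has a single level; dropped")
        next
      }
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(f)[-1])
      cols[[cv]] <- mm
    }
  }
  if (length(cols)) do.call(cbind, cols) else matrix(numeric(0), nrow(pairs), 0)
}

#' Build full and reduced design matrices for one site
#'
#' The reduced design is intercept + newborn sex (0 = female, 1 = male) +
#' clinical covariates + surrogate variables. The full design additionally
#' contains the maternal methylation main effect, its interaction with
#' sex, and its interaction with each clinical covariate column.
#'
#' @param pairs data.frame/DataFrame of per-pair covariates including
#'   \code{newborn_sex}.
#' @param svs surrogate variable matrix (samples x K) or NULL.
#' @param maternalSite INT-transformed maternal methylation vector.
#' @param covariates character vector of clinical covariate names.
#' @return list with \code{full}, \code{reduced} (model matrices over the
#'   retained rows), \code{keep} (logical complete-case mask), and
#'   \code{nDropped}.
#' @export
buildDesigns <- function(pairs, svs = NULL, maternalSite,
                         covariates = .defaultCovariates) {
  pairs <- as.data.frame(pairs)
  sex <- as.numeric(pairs$newborn_sex == "male")
  covMat <- .covariateMatrix(pairs, covariates)
  if (is.null(svs)) svs <- matrix(numeric(0), nrow(pairs), 0)
  base <- cbind("(Intercept)" = 1, sex = sex, covMat)
  keep <- stats::complete.cases(cbind(base, svs, maternalSite))
  reduced <- cbind(base, svs)[keep, , drop = FALSE]
  m <- maternalSite[keep]
  inter <- covMat[keep, , drop = FALSE] * m
  if (ncol(inter))
    colnames(inter) <- paste0("maternal:", colnames(covMat))
  full <- cbind(reduced, maternal = m, "maternal:sex" = m * sex[keep], inter)
  list(full = full, reduced = reduced, keep = keep,
       nDropped = sum(!keep))
}

#' Fit one site: likelihood-ratio and interaction tests
#'
#' Ordinary least squares for the full and reduced models; the LRT
#' statistic is \code{n*log(RSS_reduced/RSS_full)} on a chi-square with
#' df = column difference, and the interaction p-value is the Wald t of
#' the maternal-by-sex coefficient in the full model.
#'
#' @param y INT-transformed neonatal methylation vector (same length as
#'   the rows used to build the designs, i.e. already subset by
#'   \code{keep}).
#' @param designs output of \code{\link{buildDesigns}}.
#' @return one-row data.frame with effect estimate, SE, p-values and
#'   diagnostics; statistics are NA with \code{flag = "rank_deficient"}
#'   when the design loses rank after listwise deletion.
#' @export
fitSite <- function(y, designs) {
  ok <- is.finite(y)
  Xf <- designs$full[ok, , drop = FALSE]
  Xr <- designs$reduced[ok, , drop = FALSE]
  y <- y[ok]
  n <- length(y)
  na <- data.frame(beta_interaction = NA_real_, se_interaction = NA_real_,
                   p_interaction = NA_real_, lrt_stat = NA_real_,
                   p_lrt = NA_real_, r_squared = NA_real_,
                   df_residual = NA_integer_, n_used = n,
                   flag = "rank_deficient", stringsAsFactors = FALSE)
  if (n <= ncol(Xf)) return(na)
  qf <- qr(Xf)
  if (qf$rank < ncol(Xf) || qr(Xr)$rank < ncol(Xr)) return(na)
  rssF <- sum(qr.resid(qf, y)^2)
  rssR <- sum(stats::lm.fit(Xr, y)$residuals^2)
  df <- ncol(Xf) - ncol(Xr)
  stat <- n * log(rssR / rssF)
  pLrt <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  coefs <- qr.coef(qf, y)
  Rmat <- qr.R(qf)  # columns may be pivoted
  XtXinv <- chol2inv(Rmat)
  dfRes <- n - ncol(Xf)
  sigma2 <- rssF / dfRes
  j <- match("maternal:sex", colnames(Rmat))
  se <- sqrt(sigma2 * XtXinv[j, j])
  tval <- coefs["maternal:sex"] / se
  pInt <- 2 * stats::pt(-abs(tval), df = dfRes)
  data.frame(beta_interaction = unname(coefs["maternal:sex"]),
             se_interaction = se,
             p_interaction = pInt, lrt_stat = stat, p_lrt = pLrt,
             r_squared = 1 - rssF / sum((y - mean(y))^2),
             df_residual = dfRes, n_used = n, flag = "",
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR
#'
#' Step-up BH q-values; missing p-values are ignored and returned as NA.
#'
#' @param p numeric vector of p-values in [0,1]; NAs allowed.
#' @return numeric vector of q-values.
#' @export
bhFdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Epigenome-wide mother-newborn association scan
#'
#' Per site: inverse normal transformation of the maternal and neonatal
#' vectors separately, full/reduced OLS fits, likelihood-ratio test of all
#' maternal terms, and the Wald test of the maternal-by-sex interaction.
#' BH-FDR is computed jointly over all tested sites (autosomes and X);
#' the interaction FDR likewise spans all tested sites.
#'
#' @param mps a \linkS4class{MethylPairSet}.
#' @param svs surrogate variable matrix (samples x K) or NULL, estimated
#'   with the neonatal matrix as outcome.
#' @param covariates clinical covariate names (default maternal age, race,
#'   smoking, preterm, delivery); add \code{"parity"} for the
#'   parity-adjusted sensitivity analysis.
#' @param fdrThreshold significance threshold on the LRT FDR
#'   (default 0.05).
#' @return data.frame with one row per site: \code{site_id},
#'   \code{chromosome}, test statistics, \code{fdr_lrt},
#'   \code{fdr_interaction} and significance flags.
#' @export
runSiteEwas <- function(mps, svs = NULL, covariates = .defaultCovariates,
                        fdrThreshold = 0.05) {
  stopifnot(is(mps, "MethylPairSet"))
  M <- maternalBeta(mps)
  C <- neonatalBeta(mps)
  pairs <- as.data.frame(pairData(mps))
  intM <- .intRows(M)
  intC <- .intRows(C)
  rows <- vector("list", nrow(mps))
  for (j in seq_len(nrow(mps))) {
    if (attr(intM, "failed")[j] || attr(intC, "failed")[j]) {
      rows[[j]] <- data.frame(beta_interaction = NA_real_,
                              se_interaction = NA_real_,
                              p_interaction = NA_real_, lrt_stat = NA_real_,
                              p_lrt = NA_real_, r_squared = NA_real_,
                              df_residual = NA_integer_, n_used = 0L,
                              flag = "degenerate_site",
                              stringsAsFactors = FALSE)
      next
    }
    designs <- buildDesigns(pairs, svs, intM[j, ], covariates)
    rows[[j]] <- fitSite(intC[j, designs$keep], designs)
  }
  res <- do.call(rbind, rows)
  chrom <- SummarizedExperiment::rowData(mps)$chromosome
  res <- cbind(site_id = rownames(mps),
               chromosome = if (is.null(chrom)) NA_character_
                            else as.character(chrom),
               res, stringsAsFactors = FALSE)
  res$fdr_lrt <- bhFdr(res$p_lrt)
  res$fdr_interaction <- bhFdr(res$p_interaction)
  res$significant_lrt <- !is.na(res$fdr_lrt) & res$fdr_lrt < fdrThreshold
  res$significant_interaction <- !is.na(res$fdr_interaction) &
    res$fdr_interaction < fdrThreshold
  attr(res, "fdr_scope") <- "joint across autosomes and X, all tested sites"
  rownames(res) <- NULL
  res
}
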
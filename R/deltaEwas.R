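# Mother-newborn methylation differences (delta = neonatal - maternal),
# their descriptive summaries by sex and chromosome class, and the
# per-site regression of INT(delta) on newborn sex.
#
# Raw-beta deltas are used for the descriptive summaries; the regression
# uses the rank-based inverse normal transform of delta per site to limit
# outlier influence, mirroring the two-scale convention of paired-EWAS
# practice. The sex design is shared by all sites, so the scan is a single
# multi-response least-squares fit.

#' Compute the paired methylation difference matrix
#'
#' Elementwise \code{neonatal - maternal} per pair; missing wherever
#' either value is missing. Values lie in [-1, 1].
#'
#' @param mps a \linkS4class{MethylPairSet}.
#' @return numeric matrix (sites x pairs).
#' @export
computeDelta <- function(mps) {
  stopifnot(is(mps, "MethylPairSet"))
  neonatalBeta(mps) - maternalBeta(mps)
}

#' Pooled delta summaries by newborn sex and chromosome class
#'
#' Mean and SD of the raw delta pooled over site-by-pair observations,
#' split by newborn sex and autosome/X.
#'
#' @param delta matrix from \code{\link{computeDelta}}.
#' @param sex per-pair newborn sex aligned with columns.
#' @param isX per-site logical aligned with rows.
#' @return data.frame with columns \code{sex}, \code{chrom_group},
#'   \code{mean}, \code{sd}, \code{n_obs}.
#' @export
summarizeDelta <- function(delta, sex, isX) {
  stopifnot(is.matrix(delta), length(sex) == ncol(delta),
            length(isX) == nrow(delta))
  grid <- expand.grid(sex = c("female", "male"),
                      chrom_group = c("autosome", "X"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cols <- sex == grid$sex[i]
    rowsel <- if (grid$chrom_group[i] == "X") isX else !isX
    v <- delta[rowsel, cols, drop = FALSE]
    v <- v[is.finite(v)]
    data.frame(grid[i, ], mean = mean(v), sd = stats::sd(v),
               n_obs = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' EWAS of the mother-newborn methylation difference on newborn sex
#'
#' Per site, INT(delta) is regressed on newborn sex (0 = female,
#' 1 = male) plus clinical covariates and surrogate variables estimated
#' with delta as the outcome. A positive sex coefficient means the
#' mother-male difference exceeds the mother-female difference. BH-FDR is
#' computed jointly over all tested sites.
#'
#' @param delta matrix from \code{\link{computeDelta}}.
#' @param pairs per-pair covariate table including \code{newborn_sex}.
#' @param svs surrogate variable matrix (samples x K) or NULL.
#' @param chromosome optional per-site chromosome labels carried into the
#'   result.
#' @param covariates clinical covariate names.
#' @param fdrThreshold significance threshold (default 0.05).
#' @return data.frame with one row per site: \code{beta_sex}, \code{se},
#'   \code{p}, \code{fdr}, \code{direction}, \code{n_used}, \code{flag}.
#'   Sites with constant delta are flagged \code{"degenerate_site"} with
#'   missing statistics.
#' @export
runDeltaEwas <- function(delta, pairs, svs = NULL, chromosome = NULL,
                         covariates = .defaultCovariates,
                         fdrThreshold = 0.05) {
  stopifnot(is.matrix(delta))
  pairs <- as.data.frame(pairs)
  stopifnot(nrow(pairs) == ncol(delta))
  sex <- as.numeric(pairs$newborn_sex == "male")
  covMat <- .covariateMatrix(pairs, covariates)
  if (is.null(svs)) svs <- matrix(numeric(0), nrow(pairs), 0)
  X <- cbind("(Intercept)" = 1, sex = sex, covMat, svs)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)

  Z <- .intRows(delta)
  failed <- attr(Z, "failed")
  m <- nrow(delta)
  betaSex <- se <- p <- rep(NA_real_, m)
  nUsed <- integer(m)
  flag <- ifelse(failed, "degenerate_site", "")

  complete <- which(!failed & rowSums(is.na(Z)) == 0)
  jSex <- 2L
  if (length(complete)) {
    Q <- qr(X)
    Yt <- t(Z[complete, , drop = FALSE])
    coefs <- qr.coef(Q, Yt)
    res <- qr.resid(Q, Yt)
    rss <- colSums(res^2)
    dfRes <- nrow(X) - ncol(X)
    XtXinv <- chol2inv(qr.R(Q))
    jr <- match("sex", colnames(qr.R(Q)))
    sehat <- sqrt(rss / dfRes * XtXinv[jr, jr])
    tval <- coefs[jSex, ] / sehat
    betaSex[complete] <- coefs[jSex, ]
    se[complete] <- sehat
    p[complete] <- 2 * stats::pt(-abs(tval), df = dfRes)
    nUsed[complete] <- nrow(X)
  }
  incomplete <- which(!failed & rowSums(is.na(Z)) > 0)
  for (j in incomplete) {
    ok <- is.finite(Z[j, ])
    Xj <- X[ok, , drop = FALSE]
    if (sum(ok) <= ncol(Xj) || qr(Xj)$rank < ncol(Xj)) {
      flag[j] <- "rank_deficient"
      next
    }
    fit <- stats::lm.fit(Xj, Z[j, ok])
    rss <- sum(fit$residuals^2)
    dfRes <- sum(ok) - ncol(Xj)
    XtXinv <- chol2inv(qr.R(fit$qr))
    jr <- match("sex", colnames(qr.R(fit$qr)))
    sehat <- sqrt(rss / dfRes * XtXinv[jr, jr])
    betaSex[j] <- fit$coefficients["sex"]
    se[j] <- sehat
    p[j] <- 2 * stats::pt(-abs(betaSex[j] / sehat), df = dfRes)
    nUsed[j] <- sum(ok)
  }

  res <- data.frame(
    site_id = rownames(delta),
    chromosome = if (is.null(chromosome)) NA_character_
                 else as.character(chromosome),
    beta_sex = betaSex, se = se, p = p,
    fdr = bhFdr(p),
    direction = ifelse(is.na(betaSex), NA, sign(betaSex)),
    n_used = nUsed, flag = flag, stringsAsFactors = FALSE)
  res$significant <- !is.na(res$fdr) & res$fdr < fdrThreshold
  attr(res, "fdr_scope") <- "joint across autosomes and X, all tested sites"
  attr(res, "sex_coding") <- "0 = female, 1 = male"
  rownames(res) <- NULL
  res
}
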
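# Sample-wise mother-newborn Spearman correlations and the sex-matched
# derangement permutation background.
#
# Spearman rho between two complete columns equals the Pearson correlation
# of their (average-tie) ranks, so matched and shuffled correlations are
# computed from rank-standardized matrices with a single crossprod per
# site subset; with missing values the per-pair fallback drops site pairs
# with any NA.

# rank each column, then center/scale so crossprod(z1, z2)/(m-1) is the
# Spearman correlation matrix
.rankScale <- function(mat) {
  r <- apply(mat, 2, rank, ties.method = "average")
  scale(r)
}

.spearmanPair <- function(x, y) {
  stats::cor(x, y, method = "spearman", use = "pairwise.complete.obs")
}

.subsetIndex <- function(mps, subset) {
  xs <- isXSite(mps)
  switch(subset,
         all = rep(TRUE, length(xs)),
         auto = !xs,
         x = xs,
         stop("unknown subset: ", subset, call. = FALSE))
}

.rhoColumn <- function(subset) paste0("rho_", subset)

#' Per-pair genome-wide Spearman correlations
#'
#' For every mother-newborn pair, Spearman rank correlation of the paired
#' beta profiles over all shared sites, the autosomal subset, and the
#' X-chromosomal subset. Missing values are dropped pairwise within a
#' pair.
#'
#' @param mps a \linkS4class{MethylPairSet} (QC'd, site-aligned).
#' @return data.frame with one row per pair: \code{pair_id},
#'   \code{newborn_sex}, \code{rho_all}, \code{rho_auto}, \code{rho_x},
#'   and \code{source = "matched"}.
#' @export
pairSpearman <- function(mps) {
  stopifnot(is(mps, "MethylPairSet"))
  M <- maternalBeta(mps)
  C <- neonatalBeta(mps)
  out <- data.frame(pair_id = colnames(mps),
                    newborn_sex = newbornSex(mps),
                    stringsAsFactors = FALSE)
  for (subset in c("all", "auto", "x")) {
    idx <- .subsetIndex(mps, subset)
    col <- .rhoColumn(subset)
    if (!any(idx)) { out[[col]] <- NA_real_; next }
    Ms <- M[idx, , drop = FALSE]
    Cs <- C[idx, , drop = FALSE]
    if (!anyNA(Ms) && !anyNA(Cs)) {
      zM <- .rankScale(Ms)
      zC <- .rankScale(Cs)
      out[[col]] <- colSums(zM * zC) / (sum(idx) - 1)
    } else {
      out[[col]] <- vapply(seq_len(ncol(Ms)),
                           function(j) .spearmanPair(Ms[, j], Cs[, j]),
                           numeric(1))
    }
  }
  out$source <- "matched"
  out
}

# permutation of 1..k with no fixed point, by rejection sampling
.derangement <- function(k) {
  if (k < 2)
    stop("a sex stratum of size 1 admits no derangement", call. = FALSE)
  repeat {
    p <- sample.int(k)
    if (!any(p == seq_len(k))) return(p)
  }
}

#' Sex-matched shuffled-pair background correlations
#'
#' Characterizes the null of no family relatedness while preserving the
#' between-site correlation structure: within each newborn-sex stratum,
#' each iteration assigns every newborn to an unrelated mother via a
#' derangement (no newborn keeps its own mother), and the per-newborn
#' background coefficient is the mean of its shuffled-pair Spearman
#' correlations over \code{nIter} iterations.
#'
#' @param mps a \linkS4class{MethylPairSet}.
#' @param nIter number of shuffle iterations (default 10).
#' @param seed integer seed for the shuffles.
#' @return data.frame shaped like \code{\link{pairSpearman}} output with
#'   \code{source = "background"}; attribute \code{seed} records the seed.
#' @export
permutationBackground <- function(mps, nIter = 10L, seed = 1L) {
  stopifnot(is(mps, "MethylPairSet"))
  if (nIter < 1) stop("'nIter' must be at least 1", call. = FALSE)
  sex <- newbornSex(mps)
  strata <- split(seq_along(sex), sex)
  if (any(lengths(strata) < 2))
    stop("each newborn-sex stratum needs at least 2 pairs for a derangement",
         call. = FALSE)
  M <- maternalBeta(mps)
  C <- neonatalBeta(mps)
  acc <- matrix(0, ncol(mps), 3,
                dimnames = list(colnames(mps),
                                c("rho_all", "rho_auto", "rho_x")))
  # precompute full within-stratum cross-correlation matrices per subset
  crossRho <- list()
  complete <- !anyNA(M) && !anyNA(C)
  for (subset in c("all", "auto", "x")) {
    idx <- .subsetIndex(mps, subset)
    if (!any(idx)) { crossRho[[subset]] <- NULL; next }
    if (complete) {
      crossRho[[subset]] <- lapply(strata, function(ii) {
        zM <- .rankScale(M[idx, ii, drop = FALSE])
        zC <- .rankScale(C[idx, ii, drop = FALSE])
        crossprod(zM, zC) / (sum(idx) - 1)
      })
    }
  }
  withSeed(seed, {
    for (it in seq_len(nIter)) {
      for (sname in names(strata)) {
        ii <- strata[[sname]]
        k <- length(ii)
        perm <- .derangement(k)  # newborn j gets mother ii[perm[j]]
        for (subset in c("all", "auto", "x")) {
          idx <- .subsetIndex(mps, subset)
          col <- .rhoColumn(subset)
          if (!any(idx)) { acc[ii, col] <- NA_real_; next }
          if (complete) {
            rhoMat <- crossRho[[subset]][[sname]]
            acc[ii, col] <- acc[ii, col] + rhoMat[cbind(perm, seq_len(k))]
          } else {
            for (j in seq_len(k)) {
              acc[ii[j], col] <- acc[ii[j], col] +
                .spearmanPair(M[idx, ii[perm[j]]], C[idx, ii[j]])
            }
          }
        }
      }
    }
  })
  out <- data.frame(pair_id = colnames(mps), newborn_sex = sex,
                    acc / nIter, source = "background",
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "seed") <- seed
  attr(out, "nIter") <- nIter
  out
}

#' Paired t comparison of matched vs background correlations
#'
#' Student's paired t test of the per-pair difference between the matched
#' Spearman coefficient and the per-newborn background mean.
#'
#' @param matched,background outputs of \code{\link{pairSpearman}} and
#'   \code{\link{permutationBackground}} on the same pairs.
#' @param subset one of "all", "auto", "x".
#' @return list with \code{statistic}, \code{p}, \code{n},
#'   \code{group_means} (matched, background) and \code{flags}.
#' @export
compareMatchedVsBackground <- function(matched, background, subset = "all") {
  col <- .rhoColumn(match.arg(subset, c("all", "auto", "x")))
  merged <- merge(matched[, c("pair_id", col)],
                  background[, c("pair_id", col)],
                  by = "pair_id", suffixes = c(".m", ".b"))
  if (nrow(merged) != nrow(matched))
    stop("matched and background sets do not cover the same pairs",
         call. = FALSE)
  d <- merged[[paste0(col, ".m")]] - merged[[paste0(col, ".b")]]
  means <- c(matched = mean(merged[[paste0(col, ".m")]]),
             background = mean(merged[[paste0(col, ".b")]]))
  if (stats::sd(d) == 0) {
    return(list(statistic = NA_real_, p = 1, n = length(d),
                group_means = means, flags = "degenerate_variance",
                subset = subset))
  }
  tt <- stats::t.test(d)
  list(statistic = unname(tt$statistic), p = tt$p.value, n = length(d),
       group_means = means, flags = character(), subset = subset)
}

#' Two-sample t comparison of matched correlations between newborn sexes
#'
#' Welch two-sample t test of the chosen per-pair Spearman coefficient by
#' newborn sex.
#'
#' @param matched output of \code{\link{pairSpearman}}.
#' @param subset one of "all", "auto", "x".
#' @return list with \code{statistic}, \code{p}, \code{n} per group,
#'   \code{group_means} (female, male) and the test variant used.
#' @export
compareBySex <- function(matched, subset = "all") {
  col <- .rhoColumn(match.arg(subset, c("all", "auto", "x")))
  f <- matched[[col]][matched$newborn_sex == "female"]
  m <- matched[[col]][matched$newborn_sex == "male"]
  if (length(f) == 0 || length(m) == 0)
    stop("both newborn sexes must be represented", call. = FALSE)
  tt <- stats::t.test(f, m, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       n = c(female = length(f), male = length(m)),
       group_means = c(female = mean(f), male = mean(m)),
       variant = "welch", subset = subset)
}
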
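# QC filters and the rank-based inverse normal transformation.
#
# Filter thresholds follow the conventional EWAS reading "strictly more
# than": a site is removed when its detection p-value exceeds the
# threshold in over `sampleFraction` of samples; a sample is removed when
# missing strictly more than `maxMissingFraction` of sites.

#' Filter methylation sites by detection p-value and mask list
#'
#' @param beta numeric beta matrix (sites x samples).
#' @param detection optional matrix of detection p-values, same shape as
#'   \code{beta}. Required when \code{detectionThreshold} is non-NULL.
#' @param maskIds character vector of site IDs to remove regardless of
#'   detection (SNP-overlapping / cross-hybridizing probes).
#' @param detectionThreshold detection p-value above which a measurement
#'   counts as failed (default 0.01); set NULL to skip detection filtering.
#' @param sampleFraction a site is removed when it fails detection in
#'   strictly more than this fraction of samples (default 0.05).
#' @return list with \code{matrix} (filtered beta), optionally filtered
#'   \code{detection}, and \code{report} counting removals by reason.
#' @export
filterSites <- function(beta, detection = NULL, maskIds = character(),
                        detectionThreshold = 0.01, sampleFraction = 0.05) {
  stopifnot(is.matrix(beta))
  if (!is.null(detectionThreshold)) {
    if (is.null(detection))
      stop("detection p-value filtering requested but 'detection' is missing",
           call. = FALSE)
    stopifnot(detectionThreshold > 0, detectionThreshold < 1,
              sampleFraction > 0, sampleFraction < 1,
              all(dim(detection) == dim(beta)))
    failFrac <- rowMeans(detection > detectionThreshold, na.rm = TRUE)
    badDetect <- failFrac > sampleFraction
  } else {
    badDetect <- rep(FALSE, nrow(beta))
  }
  badMask <- rownames(beta) %in% maskIds & !badDetect
  keep <- !(badDetect | badMask)
  report <- list(sites_removed_detection = sum(badDetect),
                 sites_removed_mask = sum(badMask),
                 sites_retained = sum(keep),
                 sites_input = nrow(beta))
  list(matrix = beta[keep, , drop = FALSE],
       detection = if (!is.null(detection)) detection[keep, , drop = FALSE],
       report = report)
}

#' Filter samples by missing-data fraction
#'
#' @param beta numeric beta matrix (sites x samples).
#' @param maxMissingFraction a sample is removed when strictly more than
#'   this fraction of its sites is missing (default 0.02).
#' @return list with filtered \code{matrix} and a \code{report}.
#' @export
filterSamples <- function(beta, maxMissingFraction = 0.02) {
  stopifnot(is.matrix(beta), maxMissingFraction > 0, maxMissingFraction < 1)
  missFrac <- colMeans(is.na(beta))
  keep <- missFrac <= maxMissingFraction
  report <- list(samples_removed_missing = sum(!keep),
                 samples_retained = sum(keep),
                 samples_input = ncol(beta))
  list(matrix = beta[, keep, drop = FALSE], report = report)
}

#' Flag samples whose methylation-predicted sex disagrees with the record
#'
#' Predicts sex from the mean beta value over X-chromosomal sites: under
#' X-inactivation allele averaging, females sit between the unmethylated
#' active-allele level and the methylated inactive-allele level, while
#' males show the active allele only, so female means are higher at
#' island-promoter-like X sites. Samples are split by a 1-D two-means
#' clustering of the per-sample X mean.
#'
#' @param beta neonatal beta matrix (sites x samples).
#' @param chromosome per-site chromosome labels aligned with rows.
#' @param recordedSex per-sample labels, "female"/"male".
#' @param minXSites minimum number of X sites required (default 50).
#' @return character vector of flagged sample IDs; attributes
#'   \code{threshold} (cut point between cluster centers) and
#'   \code{predicted} (per-sample predicted sex).
#' @export
checkSexConsistency <- function(beta, chromosome, recordedSex,
                                minXSites = 50L) {
  stopifnot(is.matrix(beta), length(chromosome) == nrow(beta),
            length(recordedSex) == ncol(beta),
            all(recordedSex %in% c("female", "male")))
  if (ncol(beta) < 2)
    stop("at least two samples are required to form two clusters",
         call. = FALSE)
  xIdx <- which(as.character(chromosome) == "X")
  if (length(xIdx) < minXSites)
    stop(sprintf("only %d X-chromosomal sites available (need >= %d)",
                 length(xIdx), minXSites), call. = FALSE)
  xMean <- colMeans(beta[xIdx, , drop = FALSE], na.rm = TRUE)
  centers <- matrix(range(xMean), ncol = 1)
  if (diff(range(xMean)) < .Machine$double.eps^0.5)
    stop("X-chromosome means are constant; cannot split into two clusters",
         call. = FALSE)
  km <- stats::kmeans(matrix(xMean, ncol = 1), centers = centers)
  femaleCluster <- which.max(km$centers)
  predicted <- ifelse(km$cluster == femaleCluster, "female", "male")
  flagged <- colnames(beta)[predicted != recordedSex]
  structure(flagged,
            threshold = mean(km$centers),
            predicted = stats::setNames(predicted, colnames(beta)))
}

#' Rank-based inverse normal transformation
#'
#' Maps values to \code{qnorm((r - 3/8) / (n + 1/4))} where \code{r} is
#' the rank (average ranks for ties; the Blom offset). Missing values are
#' preserved; the transform is applied to the non-missing part.
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return numeric vector of normal scores, same length and NA pattern.
#' @export
#' @examples
#' inverseNormalTransform(c(3, 1, 2))  # middle value maps to 0
inverseNormalTransform <- function(x) {
  ok <- is.finite(x)
  v <- x[ok]
  if (length(v) < 2)
    stop("inverse normal transform needs at least 2 finite values",
         call. = FALSE)
  if (diff(range(v)) == 0)
    stop("inverse normal transform undefined for constant input",
         call. = FALSE)
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
  out
}

# row-wise INT over a matrix; rows that fail (constant / too few values)
# become all-NA and are reported via the "failed" attribute
.intRows <- function(mat) {
  out <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  failed <- logical(nrow(mat))
  for (j in seq_len(nrow(mat))) {
    res <- try(inverseNormalTransform(mat[j, ]), silent = TRUE)
    if (inherits(res, "try-error")) failed[j] <- TRUE else out[j, ] <- res
  }
  attr(out, "failed") <- failed
  out
}
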
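# Surrogate variable estimation: permutation parallel analysis for the
# number of components, then iteratively re-weighted residual SVD.
#
# Outcome matrices are sites x samples. The covariate design is a sample-
# level model matrix (including an intercept). Residualizing every site on
# the design leaves a residual matrix whose right singular vectors span
# candidate hidden structure; per-site weights damp sites whose residual
# variation is explained by the covariates rather than by the current
# surrogate variables, and the SVD is recomputed on the weighted residuals
# until the surrogate subspace stabilizes.

# singular values of a sites x samples matrix via the small Gram matrix
.singularValues <- function(R) {
  ev <- eigen(crossprod(R), symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev, 0))
}

#' Choose the number of surrogate variables by parallel analysis
#'
#' Residualizes the outcome on the covariate design and compares each
#' observed residual singular value with the 95th percentile of the
#' corresponding singular values from row-wise permutations of the
#' residual matrix (which destroy shared cross-sample structure while
#' preserving per-site marginals). K is the number of leading components
#' exceeding their permutation threshold.
#'
#' @param outcome numeric matrix (sites x samples), at least 50 sites.
#' @param design sample-level model matrix including an intercept.
#' @param nPerm number of permutations (default 20).
#' @param seed integer seed.
#' @param quantile permutation quantile (default 0.95).
#' @return integer K.
#' @export
estimateNumSV <- function(outcome, design, nPerm = 20L, seed = 1L,
                          quantile = 0.95) {
  stopifnot(is.matrix(outcome), is.matrix(design),
            nrow(design) == ncol(outcome))
  if (nrow(outcome) < 50)
    stop("parallel analysis needs at least 50 sites", call. = FALSE)
  if (nPerm < 1) stop("'nPerm' must be at least 1", call. = FALSE)
  if (qr(design)$rank < ncol(design))
    stop("covariate design is rank deficient", call. = FALSE)
  if (ncol(outcome) <= ncol(design) + 2)
    stop("need more samples than covariates + 2", call. = FALSE)
  R <- residualizeRows(outcome, design)
  dObs <- .singularValues(R)
  nComp <- min(dim(R)) - qr(design)$rank  # residual rank bound
  perm <- withSeed(seed, {
    vapply(seq_len(nPerm), function(b) {
      # permute the raw outcome within rows (destroys shared cross-sample
      # structure, keeps per-site marginals), then residualize so both the
      # observed and permuted matrices pass through the same projection
      Rp <- residualizeRows(t(apply(outcome, 1, sample)), design)
      .singularValues(Rp)
    }, numeric(length(dObs)))
  })
  # order-statistic threshold: the observed value of a null component
  # exceeds sorted(perm)[k] with probability (nPerm+1-k)/(nPerm+1) <= 5%
  kOrd <- ceiling((nPerm + 1) * quantile)
  if (kOrd > nPerm) kOrd <- nPerm
  thr <- apply(perm, 1, function(v) sort(v)[kOrd])
  exceeds <- dObs > thr
  K <- 0L
  for (k in seq_len(max(1, nComp))) {
    if (isTRUE(exceeds[k])) K <- k else break
  }
  K
}

# per-site F statistics for a block of columns added to a base design,
# shared across all sites (vectorized through residual projections)
.blockF <- function(Y, Xbase, Xfull) {
  rssBase <- rowSums(residualizeRows(Y, Xbase)^2)
  rssFull <- rowSums(residualizeRows(Y, Xfull)^2)
  df1 <- ncol(Xfull) - ncol(Xbase)
  df2 <- ncol(Y) - ncol(Xfull)
  pmax(0, (rssBase - rssFull) / df1) / (rssFull / df2)
}

#' Estimate surrogate variables by iteratively re-weighted residual SVD
#'
#' Starting from the top-K right singular vectors of the covariate
#' residual matrix, each iteration (1) scores every site by F statistics
#' for the surrogate-variable block (\code{F_sv}) and the model block
#' (\code{F_cov}: covariates plus any protected exposure), (2) forms
#' weights \code{w = F_sv / (F_sv + F_cov + 1)} in [0,1], (3) recomputes
#' the SVD on the row-weighted residuals, until the principal angle
#' between successive surrogate subspaces falls below \code{tol} or
#' \code{maxIter} is reached.
#'
#' The outcome is residualized on \code{design} only, never on
#' \code{protect}: surrogate variables remain free to capture confounder
#' structure correlated with the protected exposure (which is what makes
#' them able to deconfound it), while the weights suppress sites whose
#' variation is driven by the exposure itself so genuine signal is not
#' absorbed. Sites strongly associated with the exposure (e.g.
#' X-inactivation sites in a methylation-difference-by-sex analysis)
#' therefore get weights near zero.
#'
#' @param outcome numeric matrix (sites x samples).
#' @param design sample-level model matrix of adjustment covariates,
#'   including an intercept; the protected exposure must not be in it.
#' @param K number of surrogate variables; \code{K = 0} returns an empty
#'   matrix.
#' @param maxIter maximum iterations (default 50).
#' @param tol convergence tolerance on the principal-angle change
#'   (default 1e-4).
#' @param protect optional matrix (samples x p) of exposure variable(s)
#'   whose effects must not be absorbed; used only in the weight
#'   computation.
#' @return numeric matrix (samples x K) of orthonormal, mean-zero scores
#'   with columns \code{sv_1..sv_K}; attributes \code{iterations},
#'   \code{converged}, \code{finalChange}. A non-converged fit carries a
#'   warning and \code{converged = FALSE}.
#' @export
estimateSV <- function(outcome, design, K, maxIter = 50L, tol = 1e-4,
                       protect = NULL) {
  stopifnot(is.matrix(outcome), is.matrix(design),
            nrow(design) == ncol(outcome), K >= 0)
  n <- ncol(outcome)
  if (!is.null(protect)) {
    protect <- as.matrix(protect)
    stopifnot(nrow(protect) == n)
  }
  mod <- cbind(design, protect)
  rk <- qr(design)$rank
  if (rk < ncol(design) || qr(mod)$rank < ncol(mod))
    stop("covariate design is rank deficient", call. = FALSE)
  if (K >= n - qr(mod)$rank)
    stop("K must be smaller than samples minus design rank", call. = FALSE)
  empty <- matrix(numeric(0), n, 0,
                  dimnames = list(colnames(outcome), NULL))
  if (K == 0) {
    return(structure(empty, iterations = 0L, converged = TRUE,
                     finalChange = 0))
  }
  R <- residualizeRows(outcome, design)
  if (max(abs(R)) < 1e-10)
    stop("outcome has no residual structure after covariate adjustment",
         call. = FALSE)
  # initialize from the FULL-model residual (covariates + protected
  # exposure) so the starting basis is exposure-free; the weighted
  # covariate-only residual R*w in later iterations lets the surrogate
  # variables re-acquire exposure-correlated confounder components through
  # sites the weights have certified as non-signal
  sv <- svd(residualizeRows(outcome, mod), nu = 0, nv = K)$v
  penaltyBase <- function(svCur) {
    if (is.null(protect)) cbind(rep(1, n), svCur)  # penalize covariate block
    else cbind(design, svCur)                      # penalize exposure block
  }
  iter <- 0L
  change <- Inf
  while (iter < maxIter) {
    iter <- iter + 1L
    Xfull <- cbind(mod, sv)
    fSv <- .blockF(outcome, mod, Xfull)
    fCov <- .blockF(outcome, penaltyBase(sv), Xfull)
    w <- fSv / (fSv + fCov + 1)
    svNew <- svd(R * w, nu = 0, nv = K)$v
    # principal-angle change between successive subspaces
    s <- svd(crossprod(sv, svNew), nu = 0, nv = 0)$d
    change <- sqrt(max(0, 1 - min(s)^2))
    sv <- svNew
    if (change < tol) break
  }
  converged <- change < tol
  if (!converged)
    warning(sprintf(
      "surrogate variable estimation did not converge in %d iterations (change %.2g)",
      maxIter, change))
  # center and re-orthonormalize
  sv <- scale(sv, center = TRUE, scale = FALSE)
  sv <- qr.Q(qr(sv))
  dimnames(sv) <- list(colnames(outcome), sprintf("sv_%d", seq_len(K)))
  structure(sv, iterations = iter, converged = converged,
            finalChange = change)
}
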
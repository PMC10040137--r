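# Two-cohort replication: overlap of discovery-significant sites with a
# replication results table, direction concordance against a 50:50
# chi-square null, and the printed-proportion arithmetic.

#' Join discovery-significant sites onto a replication results table
#'
#' Inner join on site ID, restricted to discovery-significant sites.
#' Both tables must come from the same sex coding (0 = female, 1 = male);
#' when both carry a \code{sex_coding} attribute they are checked for
#' agreement before joining.
#'
#' @param discovery,replication results tables (e.g. from
#'   \code{\link{runDeltaEwas}}) with \code{site_id}, \code{beta_sex},
#'   \code{p}, \code{fdr}.
#' @param discoveryFdrThreshold significance threshold applied to the
#'   discovery \code{fdr} column (default 0.05).
#' @return joined data.frame with suffixed columns \code{.disc} /
#'   \code{.repl}; attribute \code{n_by_chromosome} counts the overlap by
#'   chromosome class when chromosome labels are present.
#' @export
overlapResults <- function(discovery, replication,
                           discoveryFdrThreshold = 0.05) {
  sc1 <- attr(discovery, "sex_coding")
  sc2 <- attr(replication, "sex_coding")
  if (!is.null(sc1) && !is.null(sc2) && !identical(sc1, sc2))
    stop("sex coding differs between cohorts; betas are not comparable",
         call. = FALSE)
  sig <- discovery[!is.na(discovery$fdr) &
                   discovery$fdr < discoveryFdrThreshold, , drop = FALSE]
  joined <- merge(sig, replication, by = "site_id",
                  suffixes = c(".disc", ".repl"))
  if (nrow(joined) == 0)
    stop("no overlap between discovery-significant and replication sites",
         call. = FALSE)
  if ("chromosome.disc" %in% colnames(joined)) {
    cls <- ifelse(joined$chromosome.disc == "X", "X", "autosome")
    attr(joined, "n_by_chromosome") <- table(cls)
  }
  joined
}

#' Direction concordance of replicated associations
#'
#' Among replication-significant overlapping sites (BH-FDR recomputed
#' within the overlapping set), counts agreement in the sign of the sex
#' coefficient between cohorts, reports the percentage to one decimal, and
#' tests the (consistent, inconsistent) split against 50:50 with a 1-df
#' Pearson chi-square goodness-of-fit.
#'
#' @param joined output of \code{\link{overlapResults}}.
#' @param replicationFdrThreshold threshold on the within-overlap
#'   replication FDR (default 0.05).
#' @return list with \code{n_overlap}, \code{n_sig_replication},
#'   \code{n_consistent_direction}, \code{pct_consistent},
#'   \code{chisq_stat}, \code{p}. With zero replication-significant sites
#'   the percentage and p are NA.
#' @export
concordanceSummary <- function(joined, replicationFdrThreshold = 0.05) {
  stopifnot(all(c("beta_sex.disc", "beta_sex.repl", "p.repl")
                %in% colnames(joined)))
  fdrRepl <- bhFdr(joined$p.repl)
  sig <- !is.na(fdrRepl) & fdrRepl < replicationFdrThreshold
  nSig <- sum(sig)
  if (nSig == 0) {
    return(list(n_overlap = nrow(joined), n_sig_replication = 0L,
                n_consistent_direction = 0L, pct_consistent = NA_real_,
                chisq_stat = NA_real_, p = NA_real_))
  }
  consistent <- sign(joined$beta_sex.disc[sig]) ==
    sign(joined$beta_sex.repl[sig])
  nCons <- sum(consistent)
  stat <- (2 * nCons - nSig)^2 / nSig  # Pearson GOF vs 50:50, 1 df
  list(n_overlap = nrow(joined), n_sig_replication = nSig,
       n_consistent_direction = nCons,
       pct_consistent = proportionSignificant(nCons, nSig),
       chisq_stat = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Percentage of significant sites, printed-style rounding
#'
#' \code{100 * nSignificant / nTested}, rounded half-up to one decimal as
#' in printed cohort tables.
#'
#' @param nSignificant,nTested nonnegative counts, \code{nTested > 0}.
#' @return scalar percentage.
#' @export
#' @examples
#' proportionSignificant(88051, 704552)  # 12.5
proportionSignificant <- function(nSignificant, nTested) {
  if (nTested <= 0) stop("'nTested' must be positive", call. = FALSE)
  if (nSignificant < 0 || nSignificant > nTested)
    stop("'nSignificant' must lie in [0, nTested]", call. = FALSE)
  roundHalfUp(100 * nSignificant / nTested, 1)
}
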
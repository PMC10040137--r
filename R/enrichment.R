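# Site-to-gene mapping, annotation category distributions, heritability
# stratification of top hits, and hypergeometric pathway
# over-representation against user-supplied GMT gene sets.

#' Map sites to gene symbols
#'
#' Union of gene symbols over the given sites; multi-gene annotations are
#' split on the manifest semicolon convention and intergenic sites
#' (empty gene field) contribute nothing.
#'
#' @param siteIds character vector of site IDs.
#' @param annotation data.frame/DataFrame with \code{site_id} and
#'   \code{gene} columns (or rownames as site IDs).
#' @return character vector of unique gene symbols.
#' @export
mapSitesToGenes <- function(siteIds, annotation) {
  annotation <- as.data.frame(annotation)
  ids <- if ("site_id" %in% colnames(annotation)) annotation$site_id
         else rownames(annotation)
  idx <- match(siteIds, ids)
  if (anyNA(idx))
    stop("unknown site IDs: ",
         paste(utils::head(siteIds[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  genes <- unlist(strsplit(annotation$gene[idx], ";", fixed = TRUE))
  unique(genes[!is.na(genes) & nzchar(genes)])
}

#' Category counts and proportions for a site set
#'
#' @param siteIds character vector of site IDs (nonempty).
#' @param annotation annotation table as in \code{\link{mapSitesToGenes}}.
#' @param which \code{"functional_region"} or \code{"island_relation"}.
#' @return data.frame with \code{category}, \code{count},
#'   \code{proportion} (summing to 1) over the full category universe.
#' @export
categoryDistribution <- function(siteIds, annotation,
                                 which = c("functional_region",
                                           "island_relation")) {
  which <- match.arg(which)
  if (length(siteIds) == 0) stop("empty site set", call. = FALSE)
  annotation <- as.data.frame(annotation)
  ids <- if ("site_id" %in% colnames(annotation)) annotation$site_id
         else rownames(annotation)
  idx <- match(siteIds, ids)
  if (anyNA(idx))
    stop("unknown site IDs in category distribution", call. = FALSE)
  universe <- .siteCategories[[which]]
  vals <- factor(annotation[[which]][idx], levels = universe)
  counts <- table(vals)
  data.frame(category = names(counts), count = as.integer(counts),
             proportion = as.numeric(counts) / length(siteIds),
             stringsAsFactors = FALSE)
}

#' Pearson chi-square comparison of two category distributions
#'
#' Builds the 2 x C contingency table from two count vectors sharing a
#' category universe, drops categories with zero pooled count, and returns
#' the uncorrected Pearson statistic with df = C' - 1.
#'
#' @param countsA,countsB named integer vectors (or outputs of
#'   \code{\link{categoryDistribution}}).
#' @return list with \code{statistic}, \code{df}, \code{p},
#'   \code{categories_used}.
#' @export
compareCategoryDistributions <- function(countsA, countsB) {
  toVec <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$count, x$category) else x
  }
  a <- toVec(countsA)
  b <- toVec(countsB)
  cats <- union(names(a), names(b))
  a <- ifelse(is.na(a[cats]), 0, a[cats])
  b <- ifelse(is.na(b[cats]), 0, b[cats])
  pooled <- a + b
  keep <- pooled > 0
  if (!any(keep)) stop("all category counts are zero", call. = FALSE)
  tab <- rbind(a[keep], b[keep])
  if (sum(keep) < 2 || any(rowSums(tab) == 0))
    stop("need at least two categories with counts in both groups pooled",
         call. = FALSE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- sum(keep) - 1
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE),
       categories_used = cats[keep])
}

#' Heritability of top-ranked sites vs the genome-wide background
#'
#' Ranks autosomal sites by ascending p-value of the chosen test and
#' compares the median heritability of the top \code{topN} sites with the
#' median over all autosomal sites carrying an h2 annotation.
#'
#' @param result results table with \code{site_id} and the p-value column.
#' @param annotation annotation with \code{site_id}, \code{chromosome},
#'   \code{h2}.
#' @param topN number of top sites (default 100).
#' @param pColumn name of the p-value column (default \code{"p_lrt"}).
#' @return list with \code{median_h2_top}, \code{median_h2_background},
#'   \code{n_top}, \code{n_background}.
#' @export
heritabilityStrata <- function(result, annotation, topN = 100L,
                               pColumn = "p_lrt") {
  annotation <- as.data.frame(annotation)
  stopifnot(pColumn %in% colnames(result))
  ids <- if ("site_id" %in% colnames(annotation)) annotation$site_id
         else rownames(annotation)
  idx <- match(result$site_id, ids)
  auto <- !is.na(idx) & as.character(annotation$chromosome[idx]) != "X" &
    is.finite(annotation$h2[idx]) & is.finite(result[[pColumn]])
  if (sum(auto) < topN)
    stop(sprintf("only %d annotated autosomal sites available (need >= %d)",
                 sum(auto), topN), call. = FALSE)
  h2 <- annotation$h2[idx][auto]
  p <- result[[pColumn]][auto]
  ord <- order(p)
  list(median_h2_top = stats::median(h2[ord[seq_len(topN)]]),
       median_h2_background = stats::median(h2),
       n_top = as.integer(topN), n_background = sum(auto))
}

#' Hypergeometric pathway over-representation analysis
#'
#' One-sided upper-tail hypergeometric test of the overlap between a gene
#' set and each pathway (intersected with the universe), with BH-FDR
#' across pathways. The default universe in pipeline use is the set of
#' genes mappable from the analyzed sites (conservative EWAS background).
#'
#' @param geneSet character vector of genes (must lie in the universe).
#' @param pathways named list of character vectors (e.g. from
#'   \code{\link{readGmt}}).
#' @param universe character vector of background genes.
#' @return data.frame with \code{pathway_id}, \code{n_in_map} (pathway
#'   size within the universe), \code{n_in_data} (overlap with the gene
#'   set), \code{p}, \code{fdr}, ordered by p.
#' @export
#' @examples
#' hypergeometricOra(letters[1:4], list(path = letters[1:5]), letters[1:10])
hypergeometricOra <- function(geneSet, pathways, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe", call. = FALSE)
  geneSet <- unique(geneSet)
  if (!all(geneSet %in% universe))
    stop("gene set contains genes outside the universe", call. = FALSE)
  N <- length(universe)
  q <- length(geneSet)
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(unique(pathways[[nm]]), universe)
    K <- length(pw)
    k <- length(intersect(pw, geneSet))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, q, lower.tail = FALSE)
    data.frame(pathway_id = nm, n_in_map = K, n_in_data = k, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bhFdr(res$p)
  res[order(res$p), , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' @param path path to a tab-separated GMT file (name, description,
#'   member genes).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}
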
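# Accessors and show method for MethylPairSet.

#' Accessors for MethylPairSet
#'
#' \code{maternalBeta} and \code{neonatalBeta} return the beta-value
#' matrices; \code{pairData} the per-pair sample sheet; \code{siteAnno}
#' the per-site annotation; \code{newbornSex} the newborn sex vector; and
#' \code{isXSite} a logical marking X-chromosomal sites.
#'
#' @param x a \linkS4class{MethylPairSet}.
#' @return see individual descriptions.
#' @name MethylPairSet-accessors
#' @aliases maternalBeta neonatalBeta pairData siteAnno newbornSex isXSite
NULL

#' @rdname MethylPairSet-accessors
#' @export
setGeneric("maternalBeta", function(x) standardGeneric("maternalBeta"))

#' @rdname MethylPairSet-accessors
#' @export
setGeneric("neonatalBeta", function(x) standardGeneric("neonatalBeta"))

#' @rdname MethylPairSet-accessors
#' @export
setGeneric("pairData", function(x) standardGeneric("pairData"))

#' @rdname MethylPairSet-accessors
#' @export
setGeneric("siteAnno", function(x) standardGeneric("siteAnno"))

#' @rdname MethylPairSet-accessors
#' @export
setGeneric("newbornSex", function(x) standardGeneric("newbornSex"))

#' @rdname MethylPairSet-accessors
#' @export
setGeneric("isXSite", function(x) standardGeneric("isXSite"))

#' @rdname MethylPairSet-accessors
setMethod("maternalBeta", "MethylPairSet", function(x)
  SummarizedExperiment::assay(x, "maternal"))

#' @rdname MethylPairSet-accessors
setMethod("neonatalBeta", "MethylPairSet", function(x)
  SummarizedExperiment::assay(x, "neonatal"))

#' @rdname MethylPairSet-accessors
setMethod("pairData", "MethylPairSet", function(x)
  SummarizedExperiment::colData(x))

#' @rdname MethylPairSet-accessors
setMethod("siteAnno", "MethylPairSet", function(x)
  SummarizedExperiment::rowData(x))

#' @rdname MethylPairSet-accessors
setMethod("newbornSex", "MethylPairSet", function(x)
  as.character(SummarizedExperiment::colData(x)$newborn_sex))

#' @rdname MethylPairSet-accessors
setMethod("isXSite", "MethylPairSet", function(x) {
  chrom <- SummarizedExperiment::rowData(x)$chromosome
  if (is.null(chrom))
    stop("site annotation lacks a 'chromosome' column", call. = FALSE)
  as.character(chrom) == "X"
})

setMethod("show", "MethylPairSet", function(object) {
  sex <- table(factor(newbornSex(object), c("female", "male")))
  cat("MethylPairSet with", nrow(object), "sites and",
      ncol(object), "mother-newborn pairs\n")
  cat("  newborn sex:", sex[["female"]], "female /", sex[["male"]], "male\n")
  chrom <- SummarizedExperiment::rowData(object)$chromosome
  if (!is.null(chrom))
    cat("  sites:", sum(chrom != "X"), "autosomal /",
        sum(chrom == "X"), "X-chromosomal\n")
  if (!is.null(S4Vectors::metadata(object)$truth))
    cat("  simulated cohort with generator truth in metadata(x)$truth\n")
  invisible(NULL)
})
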
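# End-to-end orchestration: cohort characteristics table, delimited-text
# I/O for matrices and sheets, run configuration, and the full pipeline
# driver with a reproducibility manifest.

#' Cohort characteristics by newborn sex
#'
#' Counts and half-up-rounded percentages per level of each categorical
#' covariate by newborn sex with a Pearson chi-square contrast, and the
#' median (range) of maternal age with a Wilcoxon rank-sum contrast.
#'
#' @param pairs pair table with \code{newborn_sex} and covariates.
#' @param bySex split by newborn sex (default TRUE); requires both sexes.
#' @param covariates categorical covariates to tabulate.
#' @return data.frame with one row per covariate level: counts and
#'   percentages (by sex when \code{bySex}) and the per-covariate test
#'   p-value on its first row.
#' @export
summarizePairs <- function(pairs, bySex = TRUE,
                           covariates = c("delivery", "preterm", "smoking",
                                          "race", "parity")) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0) stop("empty pair table", call. = FALSE)
  covariates <- intersect(covariates, colnames(pairs))
  if (bySex) {
    sexes <- unique(pairs$newborn_sex)
    if (length(sexes) < 2)
      stop("both newborn sexes are required when bySex = TRUE",
           call. = FALSE)
  }
  groups <- if (bySex) split(pairs, pairs$newborn_sex) else list(all = pairs)
  rows <- list()
  # maternal age: median (range)
  if ("maternal_age" %in% colnames(pairs)) {
    ageRow <- data.frame(variable = "maternal_age", level = "median (range)",
                         stringsAsFactors = FALSE)
    for (g in names(groups)) {
      v <- groups[[g]]$maternal_age
      ageRow[[paste0(g, "_n")]] <- NA_integer_
      ageRow[[paste0(g, "_pct")]] <- NA_real_
      ageRow[[paste0(g, "_summary")]] <-
        sprintf("%.1f (%.1f-%.1f)", stats::median(v), min(v), max(v))
    }
    ageRow$p <- if (bySex)
      stats::wilcox.test(maternal_age ~ factor(newborn_sex), data = pairs,
                         exact = FALSE)$p.value else NA_real_
    rows[["maternal_age"]] <- ageRow
  }
  for (cv in covariates) {
    f <- factor(pairs[[cv]])
    lv <- levels(f)
    block <- data.frame(variable = cv, level = lv, stringsAsFactors = FALSE)
    for (g in names(groups)) {
      fg <- factor(groups[[g]][[cv]], levels = lv)
      n <- as.integer(table(fg))
      pct <- roundHalfUp(100 * n / nrow(groups[[g]]), 1)
      block[[paste0(g, "_n")]] <- n
      block[[paste0(g, "_pct")]] <- pct
      block[[paste0(g, "_summary")]] <- sprintf("%d (%.1f%%)", n, pct)
    }
    block$p <- NA_real_
    if (bySex && length(lv) > 1) {
      tab <- table(pairs$newborn_sex, f)
      block$p[1] <- suppressWarnings(stats::chisq.test(tab)$p.value)
    }
    rows[[cv]] <- block
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# ---- delimited-text I/O -------------------------------------------------

#' Read and write sites-x-samples beta matrices as TSV
#'
#' Rows are sites, columns samples; the first column holds site IDs and
#' the header row the sample IDs.
#'
#' @param beta numeric matrix with dimnames.
#' @param path file path (".gz" suffixes are handled by R's connections).
#' @return \code{readBetaMatrix} returns a numeric matrix.
#' @export
writeBetaMatrix <- function(beta, path) {
  df <- data.frame(site_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBetaMatrix
#' @export
readBetaMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read and write tabular sheets (pair table, annotation, results) as TSV
#'
#' @param x data.frame.
#' @param path file path.
#' @return \code{readTsv} returns a data.frame.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a probe mask file (one site ID per line)
#'
#' @param path file path.
#' @return character vector of site IDs.
#' @export
readMaskFile <- function(path) {
  ids <- readLines(path)
  ids[nzchar(trimws(ids))]
}

# ---- run configuration and driver --------------------------------------

#' Assemble a pipeline run configuration
#'
#' Defaults bake in the conventional array-QC thresholds (detection
#' p 0.01 failing in over 5\% of samples; samples missing over 2\% of
#' sites), 10 permutation-background iterations, data-driven surrogate
#' variable counts, and an FDR threshold of 0.05.
#'
#' @param cohort a \linkS4class{CohortConfig} to simulate the input
#'   cohort, or NULL when file paths are given.
#' @param paths named list with \code{maternal}, \code{neonatal},
#'   \code{pairs}, \code{annotation} (TSV paths) when not simulating;
#'   optional \code{mask} (probe mask), \code{gmt} (gene sets),
#'   \code{replication} (results TSV).
#' @param outDir output directory.
#' @param detectionThreshold,detectionSampleFraction,maxMissingFraction QC
#'   thresholds.
#' @param nIter permutation-background iterations.
#' @param nSv "auto" for parallel analysis or a fixed integer count.
#' @param covariates clinical covariates; include "parity" to reproduce
#'   the parity-adjusted sensitivity analysis.
#' @param fdrThreshold significance threshold.
#' @param seed global run seed (fans out to per-stage seeds).
#' @return list of class \code{"RunConfig"}.
#' @export
runConfig <- function(cohort = NULL, paths = NULL, outDir = tempfile("run"),
                      detectionThreshold = 0.01,
                      detectionSampleFraction = 0.05,
                      maxMissingFraction = 0.02,
                      nIter = 10L, nSv = "auto",
                      covariates = .defaultCovariates,
                      fdrThreshold = 0.05, seed = 1L) {
  stopifnot(xor(is.null(cohort), is.null(paths)))
  cfg <- list(cohort = cohort, paths = paths, outDir = outDir,
              detectionThreshold = detectionThreshold,
              detectionSampleFraction = detectionSampleFraction,
              maxMissingFraction = maxMissingFraction,
              nIter = as.integer(nIter), nSv = nSv,
              covariates = covariates, fdrThreshold = fdrThreshold,
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys mirror \code{\link{runConfig}} arguments; a
#' \code{cohort:} block is passed to \code{\link{cohortConfig}}.
#'
#' @param path YAML file path.
#' @return a \code{RunConfig} list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort)) do.call(cohortConfig, y$cohort)
  args <- y[setdiff(names(y), "cohort")]
  do.call(runConfig, c(list(cohort = cohort), args))
}

.loadInputs <- function(config) {
  if (!is.null(config$cohort)) {
    return(simulateCohort(config$cohort))
  }
  p <- config$paths
  maternal <- readBetaMatrix(p$maternal)
  neonatal <- readBetaMatrix(p$neonatal)
  pairs <- readTsv(p$pairs)
  anno <- readTsv(p$annotation)
  rownames(anno) <- anno$site_id
  common <- intersect(rownames(maternal), rownames(neonatal))
  MethylPairSet(maternal[common, , drop = FALSE],
                neonatal[common, , drop = FALSE],
                pairs, S4Vectors::DataFrame(anno[common, , drop = FALSE]))
}

#' Run the full paired-methylome analysis
#'
#' Executes, in order: input load or simulation, probe-mask QC, paired
#' Spearman correlations with the sex-matched permutation background and
#' the matched-vs-background and between-sex t tests, surrogate variable
#' estimation with the neonatal matrix as outcome, the site-level LRT
#' EWAS, surrogate variable re-estimation with delta as outcome, the
#' delta-on-sex EWAS with pooled summaries, the cohort characteristics
#' table, and (when configured) replication concordance and pathway
#' over-representation. All outputs are written under
#' \code{config$outDir} and indexed in the returned manifest with MD5
#' checksums; identical seeds give byte-identical tables.
#'
#' @param config a \code{RunConfig} from \code{\link{runConfig}}.
#' @return the run manifest (list), invisibly also written as
#'   \code{manifest.json}.
#' @export
runFullPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  logLines <- character()
  stageLog <- function(stage, note) {
    logLines <<- c(logLines, sprintf("[%s] %s", stage, note))
  }
  emit <- function(name, writer) {
    path <- file.path(config$outDir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  mps <- runStage("load", .loadInputs(config))
  stageLog("load", sprintf("%d sites x %d pairs", nrow(mps), ncol(mps)))

  # QC: probe mask (detection matrices, when provided, are handled
  # upstream of pairing; see filterSites)
  mask <- if (!is.null(config$paths$mask)) readMaskFile(config$paths$mask)
          else character()
  if (length(mask)) {
    keep <- !(rownames(mps) %in% mask)
    mps <- mps[keep, ]
    stageLog("qc", sprintf("%d masked sites removed", sum(!keep)))
  }

  # pairwise correlations + permutation background
  matched <- runStage("pairs-corr", pairSpearman(mps))
  bg <- runStage("pairs-corr", permutationBackground(
    mps, nIter = config$nIter, seed = deriveSeed(config$seed, "background")))
  emit("pair_correlations.tsv",
       function(p) writeTsv(rbind(matched, bg), p))
  tests <- list(
    matched_vs_background = compareMatchedVsBackground(matched, bg, "all"),
    by_sex_all = compareBySex(matched, "all"),
    by_sex_auto = compareBySex(matched, "auto"),
    by_sex_x = compareBySex(matched, "x"))
  emit("pair_correlation_tests.json", function(p)
    jsonlite::write_json(tests, p, auto_unbox = TRUE, digits = NA))
  stageLog("pairs-corr", sprintf("matched mean rho %.3f, background %.3f",
                                 mean(matched$rho_all), mean(bg$rho_all)))

  pairs <- as.data.frame(pairData(mps))
  covDesign <- cbind("(Intercept)" = 1,
                     .covariateMatrix(pairs, config$covariates))

  # SVA with neonatal outcome, then site EWAS
  neo <- neonatalBeta(mps)
  kNeo <- if (identical(config$nSv, "auto"))
    estimateNumSV(neo, covDesign, seed = deriveSeed(config$seed, "sva-neo"))
  else as.integer(config$nSv)
  svNeo <- runStage("sva", estimateSV(neo, covDesign, kNeo))
  emit("sv_neonatal.tsv", function(p)
    writeTsv(data.frame(sample_id = colnames(mps), svNeo), p))
  stageLog("sva", sprintf("neonatal outcome: K = %d", kNeo))
  siteRes <- runStage("site-ewas",
                      runSiteEwas(mps, svNeo, config$covariates,
                                  config$fdrThreshold))
  emit("site_ewas.tsv", function(p) writeTsv(siteRes, p))
  stageLog("site-ewas", sprintf("%d/%d sites significant at FDR < %g",
                                sum(siteRes$significant_lrt), nrow(siteRes),
                                config$fdrThreshold))

  # delta: SVA with delta outcome; sex is the protected exposure (K is
  # chosen from structure beyond the full model including sex, and the
  # weighting keeps surrogate variables off exposure-driven sites)
  delta <- computeDelta(mps)
  sexCol <- cbind(sex = as.numeric(pairs$newborn_sex == "male"))
  kDelta <- if (identical(config$nSv, "auto"))
    estimateNumSV(delta, cbind(covDesign, sexCol),
                  seed = deriveSeed(config$seed, "sva-delta"))
  else as.integer(config$nSv)
  svDelta <- runStage("sva",
                      estimateSV(delta, covDesign, kDelta, protect = sexCol))
  emit("sv_delta.tsv", function(p)
    writeTsv(data.frame(sample_id = colnames(mps), svDelta), p))
  deltaRes <- runStage("delta-ewas",
                       runDeltaEwas(delta, pairs, svDelta,
                                    siteAnno(mps)$chromosome,
                                    config$covariates, config$fdrThreshold))
  emit("delta_ewas.tsv", function(p) writeTsv(deltaRes, p))
  deltaSummary <- summarizeDelta(delta, newbornSex(mps), isXSite(mps))
  emit("delta_summary.json", function(p)
    jsonlite::write_json(deltaSummary, p, auto_unbox = TRUE, digits = NA))
  stageLog("delta-ewas", sprintf("%d/%d sites significant",
                                 sum(deltaRes$significant), nrow(deltaRes)))

  # cohort characteristics
  emit("pair_characteristics.tsv", function(p)
    writeTsv(summarizePairs(pairs), p))

  # optional replication
  if (!is.null(config$paths$replication)) {
    repl <- readTsv(config$paths$replication)
    joined <- runStage("replicate", overlapResults(deltaRes, repl,
                                                   config$fdrThreshold))
    emit("replication_joined.tsv", function(p) writeTsv(joined, p))
    emit("replication_concordance.json", function(p)
      jsonlite::write_json(concordanceSummary(joined), p,
                           auto_unbox = TRUE, digits = NA))
  }

  # optional enrichment
  if (!is.null(config$paths$gmt)) {
    sig <- deltaRes$site_id[deltaRes$significant]
    anno <- siteAnno(mps)
    genes <- mapSitesToGenes(sig, anno)
    universe <- mapSitesToGenes(rownames(mps), anno)
    ora <- runStage("enrich", hypergeometricOra(
      genes, readGmt(config$paths$gmt), universe))
    emit("enrichment.tsv", function(p) writeTsv(ora, p))
  }

  emit("run_log.txt", function(p) writeLines(logLines, p))
  manifest <- list(
    package_version = as.character(utils::packageVersion("duomethyl")),
    seed = config$seed,
    stage_seeds = list(background = deriveSeed(config$seed, "background"),
                       sva_neonatal = deriveSeed(config$seed, "sva-neo"),
                       sva_delta = deriveSeed(config$seed, "sva-delta")),
    n_sites = nrow(mps), n_pairs = ncol(mps),
    n_sv = list(neonatal = kNeo, delta = kDelta),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
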
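#' @include specs.R
NULL

#' End-to-end pipeline configuration
#'
#' Exactly one input source must be supplied: a [SimulationSpec-class]
#' (synthetic study) or the three real-data paths (`dgePaths` table of
#' per-condition, per-method TSVs plus a GMT and a cofactor annotation
#' TSV).
#'
#' @slot simulation a [SimulationSpec-class] or `NULL`.
#' @slot dgePaths data.frame with columns `condition`, `method`, `path`,
#'   or `NULL`.
#' @slot gmtPath,annotationPath paths to the gene-set GMT and cofactor TSV
#'   (real-data mode).
#' @slot gsea a [GseaConfig-class].
#' @slot combineMode DE-list combination mode, see [combineMethodLists()].
#' @slot gseaMethod which DGE method's t-values feed the classical GSEA.
#' @slot topK rows per direction of the final top table.
#' @slot outDir output directory.
#' @slot seed integer master seed.
#' @export
setClass("PipelineConfig",
         representation(simulation = "ANY", dgePaths = "ANY",
                        gmtPath = "character", annotationPath = "character",
                        gsea = "GseaConfig", combineMode = "character",
                        gseaMethod = "character", topK = "integer",
                        outDir = "character", seed = "integer"))

#' @rdname PipelineConfig-class
#' @param simulation,dgePaths,gmtPath,annotationPath,gsea,combineMode,gseaMethod,topK,outDir,seed
#'   see slots.
#' @return a [PipelineConfig-class] object (validate with
#'   [validateConfig()]).
#' @export
pipelineConfig <- function(simulation = NULL, dgePaths = NULL,
                           gmtPath = NA_character_,
                           annotationPath = NA_character_,
                           gsea = gseaConfig(), combineMode = "union",
                           gseaMethod = "deseq2", topK = 10,
                           outDir = "cofgsea_out", seed = 1) {
  new("PipelineConfig", simulation = simulation, dgePaths = dgePaths,
      gmtPath = as.character(gmtPath),
      annotationPath = as.character(annotationPath), gsea = gsea,
      combineMode = as.character(combineMode),
      gseaMethod = as.character(gseaMethod), topK = as.integer(topK),
      outDir = as.character(outDir), seed = as.integer(seed))
}

#' Validate a pipeline configuration
#'
#' Collects every violation rather than stopping at the first; an empty
#' return value means the configuration is runnable.
#'
#' @param config a [PipelineConfig-class].
#' @return character vector of human-readable violations (length 0 if
#'   valid).
#' @export
validateConfig <- function(config) {
  v <- character(0)
  if (!is(config, "PipelineConfig")) return("not a PipelineConfig object")
  hasSim <- !is.null(config@simulation)
  hasReal <- !is.null(config@dgePaths)
  if (hasSim == hasReal)
    v <- c(v, "exactly one of a simulation spec or real dgePaths must be supplied")
  if (hasSim) {
    ok <- tryCatch({ validObject(config@simulation); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) v <- c(v, paste("simulation spec invalid:", ok))
  }
  if (hasReal) {
    dp <- config@dgePaths
    if (!is.data.frame(dp) ||
        !all(c("condition", "method", "path") %in% names(dp))) {
      v <- c(v, "dgePaths must be a data.frame with condition, method, path")
    } else {
      if (anyDuplicated(dp[, c("condition", "method")]))
        v <- c(v, "duplicate (condition, method) rows in dgePaths")
      if (!all(dp$method %in% c("deseq2", "voom")))
        v <- c(v, "dgePaths methods must be 'deseq2' or 'voom'")
      missing <- dp$path[!file.exists(dp$path)]
      if (length(missing))
        v <- c(v, sprintf("missing DGE table file(s): %s",
                          paste(missing, collapse = ", ")))
    }
    if (is.na(config@gmtPath) || !file.exists(config@gmtPath))
      v <- c(v, "gmtPath does not exist")
    if (is.na(config@annotationPath) || !file.exists(config@annotationPath))
      v <- c(v, "annotationPath does not exist")
  }
  ok <- tryCatch({ validObject(config@gsea); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) v <- c(v, paste("gsea config invalid:", ok))
  if (!config@combineMode %in% c("union", "intersection", "deseq2_only",
                                 "voom_only"))
    v <- c(v, sprintf("unknown combineMode '%s'", config@combineMode))
  if (!config@gseaMethod %in% c("deseq2", "voom"))
    v <- c(v, sprintf("unknown gseaMethod '%s'", config@gseaMethod))
  if (hasSim && !config@gseaMethod %in% config@simulation@methods)
    v <- c(v, sprintf("gseaMethod '%s' not among simulated methods",
                      config@gseaMethod))
  if (is.na(config@topK) || config@topK < 0) v <- c(v, "topK must be >= 0")
  if (!length(config@outDir) || is.na(config@outDir) || !nzchar(config@outDir))
    v <- c(v, "outDir must be a non-empty path")
  v
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys: `seed`, `out_dir`, `combine_mode`, `gsea_method`,
#' `top_k`, a `simulation` block (see [simulationSpec()]; snake_case
#' fields) or `dge_tables` (list of `{condition, method, path}`) plus
#' `gmt` and `annotation` paths, and a `gsea` block (`weight_exponent`,
#' `n_permutations`, `min_set_size`, `max_set_size`, `fdr_explorative`,
#' `fdr_significant`).
#'
#' @param path path to a YAML file.
#' @param outDir,seed optional overrides of the file's values.
#' @return a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path, outDir = NULL, seed = NULL) {
  x <- yaml::read_yaml(path)
  seed <- as.integer(seed %||% x$seed %||% 1)
  g <- x$gsea %||% list()
  gsea <- gseaConfig(
    weightExponent = g$weight_exponent %||% 1,
    nPermutations = g$n_permutations %||% 1000,
    minSetSize = g$min_set_size %||% 15,
    maxSetSize = g$max_set_size %||% 500,
    seed = as.integer(g$seed %||% seed),
    fdrExplorative = g$fdr_explorative %||% 0.25,
    fdrSignificant = g$fdr_significant %||% 0.05)
  sim <- NULL
  dgePaths <- NULL
  if (!is.null(x$simulation)) {
    simList <- x$simulation
    simList$seed <- as.integer(simList$seed %||% seed)
    sim <- .specFromList(simList)
  }
  if (!is.null(x$dge_tables)) {
    dgePaths <- do.call(rbind, lapply(x$dge_tables, function(t) {
      data.frame(condition = t$condition, method = t$method, path = t$path,
                 stringsAsFactors = FALSE)
    }))
  }
  pipelineConfig(simulation = sim, dgePaths = dgePaths,
                 gmtPath = x$gmt %||% NA_character_,
                 annotationPath = x$annotation %||% NA_character_,
                 gsea = gsea, combineMode = x$combine_mode %||% "union",
                 gseaMethod = x$gsea_method %||% "deseq2",
                 topK = x$top_k %||% 10,
                 outDir = outDir %||% x$out_dir %||% "cofgsea_out",
                 seed = seed)
}

#' Run the full enrichment pipeline
#'
#' Orchestrates: input acquisition (synthetic bundle or real tables) →
#' universe restriction → per-condition pre-ranked GSEA on the configured
#' method's t-values → cofactor risk ratios on every explorative-tier set →
#' DE-gene list construction and method combination → alternative
#' enrichment (percentage ranks, median-rank aggregation, per-set risk
#' ratios) → tiered and top-k report tables. All randomness derives from
#' the configured seeds, so a rerun with the same configuration produces
#' byte-identical outputs. Any stage error aborts the run with the stage
#' name, removing partial outputs.
#'
#' Outputs written to `outDir`: `gsea_results_<condition>.tsv`,
#' `gsea_report.tsv`, `cofactor_rr.tsv`, `alt_gsea_cells.tsv`,
#' `alt_gsea_summary.tsv`, `top_table.tsv`, `top_table.md`,
#' `de_gene_lists.tsv` and `manifest.json` (plus `inputs/` in simulation
#' mode).
#'
#' @param config a [PipelineConfig-class].
#' @return (invisibly) a list with all in-memory results (`bundle`,
#'   `gseaResults`, `gseaReport`, `cofactorRr`, `deLists`, `altCells`,
#'   `altSummary`, `topTable`, `manifest`).
#' @export
runFullPipeline <- function(config) {
  violations <- validateConfig(config)
  if (length(violations)) {
    stop(paste(c("invalid pipeline configuration:", violations),
               collapse = "\n  - "))
  }
  outDir <- config@outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stage <- "setup"
  result <- tryCatch({
    stage <- "inputs"
    if (!is.null(config@simulation)) {
      inputDir <- file.path(outDir, "inputs")
      bundle <- simulateStudy(config@simulation, outDir = inputDir)
      written <- c(written, list.files(inputDir, full.names = TRUE), inputDir)
      collection <- bundle$collection
      annotation <- bundle$annotation
      tables <- bundle$tables
    } else {
      dp <- config@dgePaths
      tables <- lapply(seq_len(nrow(dp)), function(i) {
        readDgeTable(dp$path[i], dp$method[i], dp$condition[i])
      })
      names(tables) <- paste(dp$condition, dp$method, sep = ".")
      collection <- readGmt(config@gmtPath)
      annotation <- readCofactorAnnotation(config@annotationPath)
      bundle <- list(collection = collection, annotation = annotation,
                     tables = tables)
    }
    measured <- unique(unlist(lapply(tables, function(t) dgeRecords(t)$gene)))
    collection <- restrictToUniverse(collection, measured)

    stage <- "gsea"
    conds <- unique(vapply(tables, conditionLabel, character(1)))
    gseaResults <- list()
    gseaReport <- list()
    cofactorRr <- list()
    for (ci in seq_along(conds)) {
      tab <- Filter(function(t) conditionLabel(t) == conds[ci] &&
                      dgeMethod(t) == config@gseaMethod, tables)[[1]]
      ranked <- makeRankedList(tab)
      cfg <- config@gsea
      cfg@seed <- .seedOffset(config@gsea@seed, ci)
      res <- runPreranked(ranked, collection, cfg)
      res <- cbind(condition = conds[ci], res)
      gseaResults[[conds[ci]]] <- res
      rep <- reportGsea(res, cfg)
      if (nrow(rep)) gseaReport[[conds[ci]]] <- rep

      stageRr <- annotateResultsWithRr(res, collection, annotation,
                                       fdrThreshold = cfg@fdrExplorative)
      if (nrow(stageRr))
        cofactorRr[[conds[ci]]] <- cbind(condition = conds[ci], stageRr)
      fn <- file.path(outDir, sprintf("gsea_results_%s.tsv", conds[ci]))
      writeGseaResults(res, fn)
      written <- c(written, fn)
    }
    gseaReport <- if (length(gseaReport)) {
      do.call(rbind, gseaReport)
    } else {
      empty <- gseaResults[[1]][0, , drop = FALSE]
      empty$tier <- character(0)
      empty
    }
    rownames(gseaReport) <- NULL
    cofactorRr <- if (length(cofactorRr)) do.call(rbind, cofactorRr) else NULL

    stage <- "de-lists"
    deLists <- buildDeGeneLists(tables, mode = config@combineMode)

    stage <- "alt-gsea"
    altCells <- runAltGsea(deLists, collection, conditions = conds)
    altSummary <- aggregateMedianRank(altCells)
    topTable <- altGseaTopTable(altSummary, k = config@topK,
                                gseaReport = gseaReport)

    stage <- "outputs"
    paths <- c(gsea_report = "gsea_report.tsv",
               cofactor_rr = "cofactor_rr.tsv",
               de_gene_lists = "de_gene_lists.tsv",
               alt_gsea_cells = "alt_gsea_cells.tsv",
               alt_gsea_summary = "alt_gsea_summary.tsv",
               top_table = "top_table.tsv")
    writeGseaResults(gseaReport, file.path(outDir, paths["gsea_report"]))
    if (!is.null(cofactorRr)) {
      .writeTsv(cofactorRr, file.path(outDir, paths["cofactor_rr"]))
    } else {
      .writeTsv(data.frame(condition = character(0), setName = character(0),
                           rr = numeric(0)),
                file.path(outDir, paths["cofactor_rr"]))
    }
    .writeTsv(deLists, file.path(outDir, paths["de_gene_lists"]))
    .writeTsv(altCells, file.path(outDir, paths["alt_gsea_cells"]))
    .writeTsv(altSummary, file.path(outDir, paths["alt_gsea_summary"]))
    .writeTsv(topTable, file.path(outDir, paths["top_table"]))
    mdPath <- file.path(outDir, "top_table.md")
    .writeTopTableMd(topTable, mdPath)
    written <- c(written, file.path(outDir, paths), mdPath)

    stage <- "manifest"
    files <- sort(setdiff(list.files(outDir, recursive = TRUE,
                                     full.names = TRUE),
                          file.path(outDir, "manifest.json")))
    manifest <- list(
      pipeline = "cofgsea::runFullPipeline",
      version = as.character(utils::packageVersion("cofgsea")),
      seed = config@seed,
      gsea = list(weight_exponent = config@gsea@weightExponent,
                  n_permutations = config@gsea@nPermutations,
                  min_set_size = config@gsea@minSetSize,
                  max_set_size = config@gsea@maxSetSize,
                  seed = config@gsea@seed),
      combine_mode = config@combineMode, gsea_method = config@gseaMethod,
      top_k = config@topK,
      simulation = if (!is.null(config@simulation))
        .specAsList(config@simulation) else NULL,
      digests = as.list(tools::md5sum(files))
    )
    names(manifest$digests) <- sub(paste0("^", outDir, "/?"), "",
                                   files)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(bundle = bundle, gseaResults = do.call(rbind, gseaResults),
         gseaReport = gseaReport, cofactorRr = cofactorRr, deLists = deLists,
         altCells = altCells, altSummary = altSummary, topTable = topTable,
         manifest = manifest)
  }, error = function(e) {
    unlink(written, recursive = TRUE)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

## Markdown rendering of the top table, with the multi-condition asterisk
## and the GSEA-overlap bold marks.
.writeTopTableMd <- function(topTable, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c("# Alternative enrichment: top gene sets per direction", "")
  for (dir in unique(topTable$direction)) {
    sub <- topTable[topTable$direction == dir, , drop = FALSE]
    lines <- c(lines, sprintf("## %sregulated gene sets", dir), "",
               "| overall rank | gene set | median rank | overrepresented in |",
               "|---|---|---|---|")
    for (i in seq_len(nrow(sub))) {
      nm <- sub$setName[i]
      if (!is.null(sub$gseaTier) && nzchar(sub$gseaTier[i]))
        nm <- sprintf("**%s**", nm)
      if (sub$multiConditionFlag[i]) nm <- paste0(nm, "\\*")
      lines <- c(lines, sprintf("| %d | %s | %s | %d condition(s) |",
                                sub$overallRank[i], nm,
                                format(sub$medianRank[i]),
                                sub$nConditionsOverrepresented[i]))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines,
             "\\* overrepresented (risk ratio > 1) in 2 or more conditions;",
             "**bold**: explorative or significant tier in the classical GSEA.")
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
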
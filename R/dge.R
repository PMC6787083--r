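.DIALECTS <- list(
  deseq2 = c(gene = "gene", log2fc = "log2FoldChange", stat = "stat",
             p = "pvalue", padj = "padj"),
  voom = c(gene = "gene", log2fc = "logFC", stat = "t",
           p = "P.Value", padj = "adj.P.Val")
)

#' Read a differential-expression statistic table
#'
#' Two column dialects are supported, mirroring the conventions of the two
#' DGE methods: `deseq2` (`gene`, `log2FoldChange`, `stat`, `pvalue`,
#' `padj`, optionally `baseMean`) and `voom` (`gene`, `logFC`, `t`,
#' `P.Value`, `adj.P.Val`). `"NA"` entries are parsed as missing values. A
#' missing required column or a duplicated gene symbol is an error.
#'
#' @param path path to a TSV file.
#' @param dialect `"deseq2"` or `"voom"`.
#' @param condition condition label to attach to the table.
#' @return a [DGETable-class].
#' @seealso [writeDgeTable()]
#' @export
readDgeTable <- function(path, dialect = c("deseq2", "voom"),
                         condition = "unspecified") {
  dialect <- match.arg(dialect)
  map <- .DIALECTS[[dialect]]
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  missing <- setdiff(unname(map), names(df))
  if (length(missing)) {
    stop(sprintf("%s table lacks required column(s): %s",
                 dialect, paste(missing, collapse = ", ")))
  }
  rec <- data.frame(gene = as.character(df[[map["gene"]]]),
                    log2fc = as.numeric(df[[map["log2fc"]]]),
                    stat = as.numeric(df[[map["stat"]]]),
                    p = as.numeric(df[[map["p"]]]),
                    padj = as.numeric(df[[map["padj"]]]),
                    stringsAsFactors = FALSE)
  if ("baseMean" %in% names(df)) rec$baseMean <- as.numeric(df$baseMean)
  if (anyDuplicated(rec$gene)) {
    stop(sprintf("duplicate gene symbol(s) in %s: %s", path,
                 paste(unique(rec$gene[duplicated(rec$gene)]), collapse = ", ")))
  }
  dgeTable(condition, dialect, rec)
}

#' Write a DGE table in its method's dialect
#'
#' @param table a [DGETable-class].
#' @param path output path.
#' @param dialect column dialect; defaults to the table's method.
#' @return `path`, invisibly.
#' @export
writeDgeTable <- function(table, path, dialect = dgeMethod(table)) {
  stopifnot(is(table, "DGETable"))
  dialect <- match.arg(dialect, c("deseq2", "voom"))
  rec <- dgeRecords(table)
  if (dialect == "deseq2") {
    out <- data.frame(gene = rec$gene,
                      baseMean = rec$baseMean %||% rep(NA_real_, nrow(rec)),
                      log2FoldChange = rec$log2fc, stat = rec$stat,
                      pvalue = rec$p, padj = rec$padj,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(gene = rec$gene, logFC = rec$log2fc, t = rec$stat,
                      P.Value = rec$p, adj.P.Val = rec$padj,
                      stringsAsFactors = FALSE)
  }
  .writeTsv(out, path)
}

#' Build the pre-ranked gene list of a DGE table
#'
#' Genes are ordered by decreasing ranking statistic (the t-value); genes
#' with a missing statistic are dropped with a message, and exact ties are
#' broken by gene symbol so the ordering is deterministic.
#'
#' @param table a [DGETable-class].
#' @return a named numeric vector (names = genes, values = statistics),
#'   sorted in decreasing order — the "ranked list" consumed by
#'   [runPreranked()] and [enrichmentScore()].
#' @export
makeRankedList <- function(table) {
  stopifnot(is(table, "DGETable"))
  rec <- dgeRecords(table)
  miss <- is.na(rec$stat)
  if (any(miss)) {
    message(sprintf("makeRankedList: dropping %d gene(s) with missing statistic",
                    sum(miss)))
    rec <- rec[!miss, , drop = FALSE]
  }
  if (nrow(rec) < 2L) stop("fewer than 2 genes with a usable ranking statistic")
  ord <- order(-rec$stat, rec$gene)
  stats <- rec$stat[ord]
  names(stats) <- rec$gene[ord]
  stats
}

#' Export a ranked list to RNK format
#'
#' @param ranked named numeric vector as returned by [makeRankedList()].
#' @param path output path (`gene<TAB>score`, no header).
#' @return `path`, invisibly.
#' @export
writeRnk <- function(ranked, path) {
  lines <- paste(names(ranked), .fmtNum(unname(ranked)), sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a ranked list from RNK format
#' @param path path to an RNK file.
#' @return a named numeric vector sorted in decreasing order.
#' @export
readRnk <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("gene", "score"))
  stats <- as.numeric(df$score)
  names(stats) <- df$gene
  sort(stats, decreasing = TRUE)
}

#' Select differentially expressed genes by the dual inclusion criteria
#'
#' A gene is differentially expressed iff
#' `(|log2fc| > 0.5 AND p < 0.1) OR p < 0.05`, all inequalities strict —
#' a compromise between statistical significance (low p) and biological
#' relevance (large change). The nominal p-value drives the criteria by
#' default (`pColumn = "p"`); set `pColumn = "padj"` to use the adjusted
#' one. The direction is the sign of the log2 fold change; a gene with
#' log2fc exactly 0 that passes on p alone belongs to neither directional
#' list and is dropped with a message, as are genes with missing values.
#'
#' @param table a [DGETable-class].
#' @param direction `"up"` or `"down"`.
#' @param lfcThreshold,pRelaxed,pStrict the three criterion constants
#'   (defaults 0.5, 0.1, 0.05).
#' @param pColumn `"p"` (nominal, default) or `"padj"`.
#' @return character vector of gene symbols.
#' @export
selectDeGenes <- function(table, direction = c("up", "down"),
                          lfcThreshold = 0.5, pRelaxed = 0.1, pStrict = 0.05,
                          pColumn = c("p", "padj")) {
  stopifnot(is(table, "DGETable"))
  direction <- match.arg(direction)
  pColumn <- match.arg(pColumn)
  rec <- dgeRecords(table)
  p <- rec[[pColumn]]
  lfc <- rec$log2fc
  usable <- !is.na(p) & !is.na(lfc)
  de <- usable & ((abs(lfc) > lfcThreshold & p < pRelaxed) | p < pStrict)
  zero <- de & lfc == 0
  if (any(zero)) {
    message(sprintf(paste0("selectDeGenes: %d gene(s) pass on p alone with ",
                           "log2fc == 0; excluded from both directions"),
                    sum(zero)))
  }
  keep <- if (direction == "up") de & lfc > 0 else de & lfc < 0
  rec$gene[keep]
}

#' Combine per-method DE gene lists
#'
#' Merges the up/down lists obtained from several DGE methods for one
#' condition. A gene qualifying "up" in one method and "down" in another is
#' contradictory and is excluded from both directions (logged). Provenance
#' records which method(s) supported each retained gene.
#'
#' @param perMethod named list (method -> `list(up = ..., down = ...)`).
#' @param mode `"union"` (default), `"intersection"`, `"deseq2_only"` or
#'   `"voom_only"`.
#' @return list with `up`, `down` (character vectors), `conflicts`
#'   (genes removed as contradictory) and `provenance` (data.frame with
#'   columns `gene`, `direction`, `methods`).
#' @export
combineMethodLists <- function(perMethod,
                               mode = c("union", "intersection",
                                        "deseq2_only", "voom_only")) {
  mode <- match.arg(mode)
  methods <- names(perMethod)
  if (is.null(methods) || !length(methods)) stop("perMethod must be named")
  ups <- lapply(perMethod, `[[`, "up")
  downs <- lapply(perMethod, `[[`, "down")
  conflicts <- intersect(unique(unlist(ups)), unique(unlist(downs)))
  if (length(conflicts)) {
    message(sprintf("combineMethodLists: %d gene(s) with conflicting direction excluded",
                    length(conflicts)))
  }
  pick <- function(lists) {
    merged <- switch(mode,
      union = unique(unlist(lists)),
      intersection = Reduce(intersect, lists),
      deseq2_only = lists[["deseq2"]] %||%
        stop("mode 'deseq2_only' but no 'deseq2' list supplied"),
      voom_only = lists[["voom"]] %||%
        stop("mode 'voom_only' but no 'voom' list supplied"))
    sort(setdiff(merged, conflicts))
  }
  up <- pick(ups)
  down <- pick(downs)
  prov <- function(genes, lists, dirLabel) {
    if (!length(genes)) return(NULL)
    data.frame(gene = genes, direction = dirLabel,
               methods = vapply(genes, function(g) {
                 paste(methods[vapply(lists, function(l) g %in% l, logical(1))],
                       collapse = ";")
               }, character(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  provenance <- rbind(prov(up, ups, "up"), prov(down, downs, "down"))
  if (is.null(provenance)) {
    provenance <- data.frame(gene = character(0), direction = character(0),
                             methods = character(0), stringsAsFactors = FALSE)
  }
  list(up = up, down = down, conflicts = sort(conflicts),
       provenance = provenance)
}

#' Build the per-condition DE gene lists of a whole study
#'
#' Applies [selectDeGenes()] to every table and [combineMethodLists()] per
#' condition, yielding the long-format input of [runAltGsea()].
#'
#' @param tables named list of [DGETable-class] (e.g. from
#'   [generateDgeTables()]).
#' @param mode method-combination mode, see [combineMethodLists()].
#' @param ... further arguments passed to [selectDeGenes()].
#' @return data.frame with columns `condition`, `direction`, `gene`,
#'   `methods`.
#' @export
buildDeGeneLists <- function(tables, mode = "union", ...) {
  conds <- unique(vapply(tables, conditionLabel, character(1)))
  out <- lapply(conds, function(cond) {
    sub <- tables[vapply(tables, function(t) conditionLabel(t) == cond,
                         logical(1))]
    perMethod <- lapply(sub, function(t) {
      list(up = selectDeGenes(t, "up", ...),
           down = selectDeGenes(t, "down", ...))
    })
    names(perMethod) <- vapply(sub, dgeMethod, character(1))
    combined <- combineMethodLists(perMethod, mode = mode)
    if (!nrow(combined$provenance)) return(NULL)
    cbind(condition = cond, combined$provenance)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(condition = character(0), gene = character(0),
                      direction = character(0), methods = character(0),
                      stringsAsFactors = FALSE)
  }
  out[, c("condition", "direction", "gene", "methods")]
}
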
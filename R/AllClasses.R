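#' @include AAA-generics.R
NULL

#' An ordered collection of named gene sets
#'
#' Gene sets are stored as a named list of character vectors of gene
#' symbols (case-sensitive), with one free-text description per set. The
#' collection's *universe* — the exact union of all members — acts as the
#' "metabolic genes" denominator of the alternative enrichment analysis.
#'
#' @slot sets named list of character vectors (unique symbols within a set).
#' @slot descriptions character vector parallel to `sets`.
#'
#' @seealso [readGmt()], [writeGmt()], [restrictToUniverse()],
#'   [buildCofactorSets()]
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  s <- object@sets
  msg <- character(0)
  if (length(s)) {
    nm <- names(s)
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
      msg <- c(msg, "all gene sets must be named")
    else if (anyDuplicated(nm))
      msg <- c(msg, "gene set names must be unique")
    if (!all(vapply(s, is.character, logical(1))))
      msg <- c(msg, "gene set members must be character vectors")
    else {
      if (any(vapply(s, anyDuplicated, integer(1)) > 0L))
        msg <- c(msg, "duplicate members within a gene set")
      if (any(vapply(s, anyNA, logical(1))))
        msg <- c(msg, "NA gene symbols are not allowed")
    }
  }
  if (length(object@descriptions) != length(s))
    msg <- c(msg, "descriptions must be parallel to sets")
  if (length(msg)) msg else TRUE
})

#' Construct a gene set collection
#'
#' @param sets named list of character vectors of gene symbols.
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled empty string by default).
#' @return a [GeneSetCollection-class] object.
#' @examples
#' gsc <- geneSetCollection(list(S1 = c("A", "B"), S2 = c("B", "C")))
#' universe(gsc)
#' @export
geneSetCollection <- function(sets = list(), descriptions = NULL) {
  sets <- lapply(sets, as.character)
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname accessors
#' @export
setMethod("setDescriptions", "GeneSetCollection", function(x) x@descriptions)

#' @rdname accessors
#' @export
setMethod("universe", "GeneSetCollection", function(x) {
  if (!length(x@sets)) return(character(0))
  sort(unique(unlist(x@sets, use.names = FALSE)))
})

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @export
setMethod("show", "GeneSetCollection", function(object) {
  n <- length(object@sets)
  cat(sprintf("GeneSetCollection with %d set(s), universe of %d gene(s)\n",
              n, length(universe(object))))
  if (n) {
    k <- min(n, 5L)
    for (i in seq_len(k)) {
      cat(sprintf("  %s (%d genes)\n",
                  names(object@sets)[i], length(object@sets[[i]])))
    }
    if (n > k) cat(sprintf("  ... and %d more\n", n - k))
  }
})

#' Per-gene cofactor-class membership flags
#'
#' Records, for every gene of a universe, whether its product catalyses
#' reactions involving coenzyme A (`isCoa`), any reaction involving
#' NAD(P)+/NAD(P)H (`isNadphMain`), or only NAD(P)(H) redox chemistry
#' (`isNadphRedox`). Redox membership implies main membership: the redox
#' reactions are a subset of all NAD(P)(H)-involving reactions.
#'
#' @slot gene character vector of unique gene symbols.
#' @slot isCoa,isNadphMain,isNadphRedox logical vectors parallel to `gene`.
#' @export
setClass("CofactorAnnotation",
         representation(gene = "character", isCoa = "logical",
                        isNadphMain = "logical", isNadphRedox = "logical"))

setValidity("CofactorAnnotation", function(object) {
  n <- length(object@gene)
  msg <- character(0)
  if (anyDuplicated(object@gene)) msg <- c(msg, "duplicate gene symbols")
  if (anyNA(object@gene)) msg <- c(msg, "NA gene symbols")
  for (fl in c("isCoa", "isNadphMain", "isNadphRedox")) {
    v <- slot(object, fl)
    if (length(v) != n) msg <- c(msg, sprintf("%s must be parallel to gene", fl))
    if (anyNA(v)) msg <- c(msg, sprintf("%s must not contain NA", fl))
  }
  if (length(object@isNadphRedox) == n && length(object@isNadphMain) == n &&
      any(object@isNadphRedox & !object@isNadphMain))
    msg <- c(msg, "isNadphRedox implies isNadphMain (redox is a subset of main)")
  if (length(msg)) msg else TRUE
})

#' Construct a cofactor annotation
#'
#' @param gene character vector of gene symbols.
#' @param isCoa,isNadphMain,isNadphRedox logical flags parallel to `gene`.
#' @return a [CofactorAnnotation-class] object.
#' @export
cofactorAnnotation <- function(gene = character(0),
                               isCoa = logical(length(gene)),
                               isNadphMain = logical(length(gene)),
                               isNadphRedox = logical(length(gene))) {
  new("CofactorAnnotation", gene = as.character(gene),
      isCoa = as.logical(isCoa), isNadphMain = as.logical(isNadphMain),
      isNadphRedox = as.logical(isNadphRedox))
}

#' @rdname accessors
#' @export
setMethod("cofactorGenes", "CofactorAnnotation",
          function(x, classes = c("coa", "nadph_main")) {
  classes <- match.arg(classes, c("coa", "nadph_main", "nadph_redox"),
                       several.ok = TRUE)
  keep <- rep(FALSE, length(x@gene))
  if ("coa" %in% classes) keep <- keep | x@isCoa
  if ("nadph_main" %in% classes) keep <- keep | x@isNadphMain
  if ("nadph_redox" %in% classes) keep <- keep | x@isNadphRedox
  x@gene[keep]
})

#' @export
setMethod("length", "CofactorAnnotation", function(x) length(x@gene))

#' @export
setMethod("show", "CofactorAnnotation", function(object) {
  cat(sprintf(paste0("CofactorAnnotation: %d gene(s); CoA: %d, ",
                     "NAD(P)(H) main: %d, NAD(P)(H) redox: %d\n"),
              length(object@gene), sum(object@isCoa),
              sum(object@isNadphMain), sum(object@isNadphRedox)))
})

#' Coerce a CofactorAnnotation to a data.frame
#'
#' @param x a [CofactorAnnotation-class].
#' @param ... ignored.
#' @export
as.data.frame.CofactorAnnotation <- function(x, ...) {
  data.frame(gene = x@gene, is_coa = x@isCoa, is_nadph_main = x@isNadphMain,
             is_nadph_redox = x@isNadphRedox, stringsAsFactors = FALSE)
}

#' Per-condition differential gene expression statistics
#'
#' One table per (condition x method). The `records` data.frame holds one
#' row per gene with the dialect-independent columns `gene`, `log2fc`,
#' `stat` (the ranking t-statistic), `p` and `padj`; `baseMean` is kept
#' when present (DESeq2 dialect). `NA` marks missing values, which are
#' excluded from ranking and differential-expression selection rather than
#' imputed.
#'
#' @slot condition condition label, e.g. `"LF_fed"`.
#' @slot method DGE dialect, `"deseq2"` or `"voom"`.
#' @slot records data.frame of per-gene statistics.
#' @export
setClass("DGETable",
         representation(condition = "character", method = "character",
                        records = "data.frame"))

setValidity("DGETable", function(object) {
  msg <- character(0)
  if (length(object@condition) != 1L || is.na(object@condition))
    msg <- c(msg, "condition must be a single label")
  if (length(object@method) != 1L || !object@method %in% c("deseq2", "voom"))
    msg <- c(msg, "method must be 'deseq2' or 'voom'")
  req <- c("gene", "log2fc", "stat", "p", "padj")
  missing <- setdiff(req, names(object@records))
  if (length(missing)) {
    msg <- c(msg, sprintf("records lack column(s): %s",
                          paste(missing, collapse = ", ")))
  } else {
    if (anyDuplicated(object@records$gene))
      msg <- c(msg, "duplicate gene symbols in records")
    for (col in c("p", "padj")) {
      v <- object@records[[col]]
      if (any(!is.na(v) & (v < 0 | v > 1)))
        msg <- c(msg, sprintf("%s values must lie in [0, 1]", col))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DGE table
#'
#' @param condition condition label.
#' @param method DGE dialect, `"deseq2"` or `"voom"`.
#' @param records data.frame with columns `gene`, `log2fc`, `stat`, `p`,
#'   `padj` (and optionally `baseMean`).
#' @return a [DGETable-class] object.
#' @export
dgeTable <- function(condition, method, records) {
  rownames(records) <- NULL
  new("DGETable", condition = as.character(condition),
      method = as.character(method), records = records)
}

#' @rdname accessors
#' @export
setMethod("conditionLabel", "DGETable", function(x) x@condition)

#' @rdname accessors
#' @export
setMethod("dgeMethod", "DGETable", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("dgeRecords", "DGETable", function(x) x@records)

#' @export
setMethod("show", "DGETable", function(object) {
  cat(sprintf("DGETable [%s, %s]: %d gene(s), %d with missing p\n",
              object@condition, object@method, nrow(object@records),
              sum(is.na(object@records$p))))
})
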
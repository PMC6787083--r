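#' Read a gene-set collection from a GMT file
#'
#' GMT is the standard tab-separated gene-set exchange format: one set per
#' line as `name<TAB>description<TAB>member1<TAB>member2...`. Member order
#' is preserved; duplicate members within a line are removed with a
#' warning; a duplicate set name or a line with fewer than three fields is
#' an error (the latter reported with its line number).
#'
#' @param path path to a GMT file.
#' @return a [GeneSetCollection-class].
#' @seealso [writeGmt()]
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(geneSetCollection())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- lineNo[which(nf < 3L)[1]]
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", bad))
  }
  nm <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate gene set name(s) in GMT: %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  desc <- vapply(fields, `[`, character(1), 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  dup <- vapply(members, anyDuplicated, integer(1)) > 0L
  if (any(dup)) {
    warning(sprintf("duplicate members removed in set(s): %s",
                    paste(nm[dup], collapse = ", ")))
    members <- lapply(members, function(m) m[!duplicated(m)])
  }
  names(members) <- nm
  names(desc) <- nm
  geneSetCollection(members, desc)
}

#' Write a gene-set collection to a GMT file
#'
#' Members are written in lexicographic order so that equal collections
#' always serialize to byte-identical files.
#'
#' @param collection a [GeneSetCollection-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(collection, path) {
  stopifnot(is(collection, "GeneSetCollection"))
  sets <- geneSets(collection)
  desc <- setDescriptions(collection)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[[i]], sort(sets[[i]])), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Build the three cofactor gene sets from an annotation
#'
#' Projects the per-gene flags into the gene sets "CoA gene set" (enzymes
#' catalysing reactions involving coenzyme A), "NAD(P)(H) main" (all
#' reactions involving NAD(P)+/NAD(P)H) and "NAD(P)(H) redox" (only the
#' NAD(P)(H) redox reactions; always a subset of the main set). A class
#' with zero genes yields an empty set, retained with a warning.
#'
#' @param annotation a [CofactorAnnotation-class].
#' @return a [GeneSetCollection-class] with the three sets.
#' @export
buildCofactorSets <- function(annotation) {
  stopifnot(is(annotation, "CofactorAnnotation"))
  if (!length(annotation@gene)) stop("annotation is empty")
  sets <- list(
    "CoA gene set" = annotation@gene[annotation@isCoa],
    "NAD(P)(H) main" = annotation@gene[annotation@isNadphMain],
    "NAD(P)(H) redox" = annotation@gene[annotation@isNadphRedox]
  )
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) {
    warning(sprintf("cofactor class(es) with zero genes: %s",
                    paste(empty, collapse = ", ")))
  }
  geneSetCollection(sets, c("genes of CoA-involving reactions",
                            "genes of all NAD(P)(H)-involving reactions",
                            "genes of NAD(P)(H) redox reactions"))
}

#' Names of the three built-in cofactor gene sets
#' @return character vector of length 3.
#' @export
cofactorSetNames <- function() {
  c("CoA gene set", "NAD(P)(H) main", "NAD(P)(H) redox")
}

#' Rank gene sets by their percentage of cofactor genes
#'
#' For each set, the percentage of members flagged as CoA or NAD(P)(H)-main
#' genes is computed and sets are sorted by decreasing percentage (ties
#' broken by set name). Sets ranked within the top `ceil(n/2)` are flagged
#' as the top half. Empty sets have no defined percentage and are excluded
#' with a warning. By default the three built-in cofactor sets are excluded
#' from their own ranking.
#'
#' @param collection a [GeneSetCollection-class] restricted to a universe
#'   covered by `annotation`.
#' @param annotation a [CofactorAnnotation-class].
#' @param excludeSets set names excluded from the ranking.
#' @return data.frame with columns `setName`, `nMembers`, `nCofactor`,
#'   `percentage`, `rank`, `topHalf`, ordered by rank.
#' @export
cofactorPercentageRanking <- function(collection, annotation,
                                      excludeSets = cofactorSetNames()) {
  stopifnot(is(collection, "GeneSetCollection"),
            is(annotation, "CofactorAnnotation"))
  sets <- geneSets(collection)
  sets <- sets[!names(sets) %in% excludeSets]
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sprintf("excluding empty set(s) with undefined percentage: %s",
                    paste(names(sets)[empty], collapse = ", ")))
    sets <- sets[!empty]
  }
  cof <- cofactorGenes(annotation, c("coa", "nadph_main"))
  n <- lengths(sets)
  k <- vapply(sets, function(m) length(intersect(m, cof)), integer(1))
  pct <- 100 * k / n
  ord <- order(-pct, names(sets))
  out <- data.frame(setName = names(sets)[ord], nMembers = n[ord],
                    nCofactor = k[ord], percentage = pct[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$rank <- seq_len(nrow(out))
  out$topHalf <- out$rank <= ceiling(nrow(out) / 2)
  out
}

#' Restrict a collection to a gene universe
#'
#' Intersects every set with `genes` (e.g. the genes actually measured in
#' the DGE tables), drops sets emptied by the restriction with a warning,
#' and recomputes the universe.
#'
#' @param collection a [GeneSetCollection-class].
#' @param genes character vector of gene symbols.
#' @return a [GeneSetCollection-class].
#' @export
restrictToUniverse <- function(collection, genes) {
  stopifnot(is(collection, "GeneSetCollection"))
  sets <- lapply(geneSets(collection), function(m) m[m %in% genes])
  dropped <- names(sets)[lengths(sets) == 0L]
  if (length(dropped)) {
    warning(sprintf("dropping %d set(s) emptied by universe restriction: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  keep <- lengths(sets) > 0L
  geneSetCollection(sets[keep], setDescriptions(collection)[keep])
}

#' Translate gene identifiers in a collection
#'
#' Gene identity is case-sensitive symbol matching throughout the package;
#' this helper applies an explicit two-column mapping (`from`, `to`) to a
#' collection, e.g. to align probe or ensembl identifiers in a GMT with the
#' symbols used in the DGE tables. Unmapped symbols are kept unchanged
#' (`keepUnmapped = TRUE`, default) or dropped; duplicate targets within a
#' set are collapsed.
#'
#' @param collection a [GeneSetCollection-class].
#' @param mapping data.frame with columns `from` and `to`, or the path of a
#'   two-column TSV (header `from`, `to`).
#' @param keepUnmapped keep symbols without a mapping entry?
#' @return a [GeneSetCollection-class] with translated members.
#' @export
applyGeneMapping <- function(collection, mapping, keepUnmapped = TRUE) {
  stopifnot(is(collection, "GeneSetCollection"))
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- utils::read.delim(mapping, stringsAsFactors = FALSE)
  }
  if (!all(c("from", "to") %in% names(mapping))) {
    stop("mapping must have columns 'from' and 'to'")
  }
  if (anyDuplicated(mapping$from)) {
    stop("mapping 'from' column must be unique")
  }
  sets <- lapply(geneSets(collection), function(m) {
    idx <- match(m, mapping$from)
    out <- ifelse(is.na(idx), if (keepUnmapped) m else NA_character_,
                  mapping$to[idx])
    unique(out[!is.na(out)])
  })
  dropped <- names(sets)[lengths(sets) == 0L]
  if (length(dropped)) {
    warning(sprintf("set(s) emptied by mapping: %s",
                    paste(dropped, collapse = ", ")))
  }
  keep <- lengths(sets) > 0L
  geneSetCollection(sets[keep], setDescriptions(collection)[keep])
}

#' Read and write cofactor annotation TSV
#'
#' The interchange format is a TSV with columns `gene`, `is_coa`,
#' `is_nadph_main`, `is_nadph_redox` (flags as 0/1).
#'
#' @param path file path.
#' @return `readCofactorAnnotation` returns a [CofactorAnnotation-class];
#'   `writeCofactorAnnotation` returns `path` invisibly.
#' @export
readCofactorAnnotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "is_coa", "is_nadph_main", "is_nadph_redox")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop(sprintf("annotation TSV lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  cofactorAnnotation(df$gene, df$is_coa > 0, df$is_nadph_main > 0,
                     df$is_nadph_redox > 0)
}

#' @rdname readCofactorAnnotation
#' @param annotation a [CofactorAnnotation-class].
#' @export
writeCofactorAnnotation <- function(annotation, path) {
  df <- as.data.frame(annotation)
  df$is_coa <- as.integer(df$is_coa)
  df$is_nadph_main <- as.integer(df$is_nadph_main)
  df$is_nadph_redox <- as.integer(df$is_nadph_redox)
  .writeTsv(df, path)
}
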
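## Random-stream layout (fixed offsets from the spec seed):
##   +0                universe & cofactor flags
##   +1                gene-set collection
##   +2 + s            responsive membership of planted signal s
##   +1000 + 100*c + m table for condition index c, method index m
.STREAM_COLLECTION <- 1L
.STREAM_SIGNALS <- 2L
.STREAM_TABLES <- 1000L

#' Generate a synthetic gene universe with cofactor flags
#'
#' Gene symbols are synthetic (`G000001`, `G000002`, ...). The CoA and
#' NAD(P)(H)-main flags are drawn independently per gene at their class
#' fractions; the redox flag is drawn among main-flagged genes at the third
#' fraction, which enforces the redox-subset-of-main invariant.
#'
#' @param spec a [SimulationSpec-class].
#' @return list with elements `genes` (character) and `annotation`
#'   (a [CofactorAnnotation-class]).
#' @export
generateUniverse <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  validObject(spec)
  n <- spec@nGenes
  if (n == 0L) {
    return(list(genes = character(0), annotation = cofactorAnnotation()))
  }
  genes <- sprintf("G%06d", seq_len(n))
  f <- spec@cofactorFraction
  ann <- withr::with_seed(.seedOffset(spec@seed, 0L), {
    isCoa <- stats::runif(n) < f[1]
    isMain <- stats::runif(n) < f[2]
    isRedox <- isMain & (stats::runif(n) < f[3])
    cofactorAnnotation(genes, isCoa, isMain, isRedox)
  })
  list(genes = genes, annotation = ann)
}

#' Generate a synthetic gene-set collection
#'
#' Set sizes are uniform over `setSizeRange`; members are sampled without
#' replacement within a set, and sets may overlap.
#'
#' @param genes character vector, the gene universe.
#' @param spec a [SimulationSpec-class].
#' @return a [GeneSetCollection-class] with sets `SET0001`, `SET0002`, ...
#' @export
generateCollection <- function(genes, spec) {
  stopifnot(is(spec, "SimulationSpec"))
  validObject(spec)
  if (!length(genes)) stop("gene universe is empty")
  r <- spec@setSizeRange
  if (r[2] > length(genes))
    stop("setSizeRange max exceeds the number of genes in the universe")
  nSets <- spec@nSets
  withr::with_seed(.seedOffset(spec@seed, .STREAM_COLLECTION), {
    sizeChoices <- seq.int(r[1], r[2])
    sizes <- sizeChoices[sample.int(length(sizeChoices), nSets, replace = TRUE)]
    sets <- lapply(sizes, function(k) genes[sample.int(length(genes), k)])
    names(sets) <- sprintf("SET%04d", seq_len(nSets))
    geneSetCollection(sets, rep("synthetic gene set", nSets))
  })
}

## responsive members per planted signal, drawn once so membership is shared
## across the signal's conditions and both DGE methods
.responsiveMembers <- function(collection, spec) {
  sets <- geneSets(collection)
  lapply(seq_along(spec@planted), function(s) {
    sig <- spec@planted[[s]]
    members <- sets[[sig@targetSet]]
    k <- ceiling(sig@responsiveFraction * length(members))
    withr::with_seed(.seedOffset(spec@seed, .STREAM_SIGNALS + s), {
      members[sample.int(length(members), k)]
    })
  })
}

#' Generate per-condition, per-method DGE statistic tables
#'
#' Null genes draw their ranking statistic from Student-t(`df`); the
#' two-sided p-value is the analytic tail probability of that statistic,
#' and the null log2 fold change is centred Gaussian noise. Responsive
#' genes of a planted signal have their t-statistic shifted by `+delta`
#' (up) or `-delta` (down), the p-value recomputed from the shifted value,
#' and a log2 fold change whose sign matches the realized sign of the
#' shifted statistic (mean magnitude `delta * nullSigmaLfc`). Adjusted
#' p-values are Benjamini-Hochberg within each table. The two methods of a
#' condition share planted membership but use independent noise draws.
#'
#' @param genes gene universe (character).
#' @param collection the [GeneSetCollection-class] the planted signals
#'   refer to.
#' @param spec a [SimulationSpec-class].
#' @return named list of [DGETable-class], one per (condition x method),
#'   named `"<condition>.<method>"`.
#' @export
generateDgeTables <- function(genes, collection, spec) {
  stopifnot(is(spec, "SimulationSpec"), is(collection, "GeneSetCollection"))
  validObject(spec)
  setNamesAll <- names(geneSets(collection))
  for (sig in spec@planted) {
    if (!sig@targetSet %in% setNamesAll)
      stop(sprintf("planted target set '%s' not in collection", sig@targetSet))
    bad <- setdiff(sig@conditions, spec@conditionLabels)
    if (length(bad))
      stop(sprintf("unknown condition label(s) in planted signal: %s",
                   paste(bad, collapse = ", ")))
  }
  n <- length(genes)
  responsive <- .responsiveMembers(collection, spec)
  geneIndex <- seq_len(n)
  names(geneIndex) <- genes

  tables <- list()
  for (ci in seq_along(spec@conditionLabels)) {
    cond <- spec@conditionLabels[ci]
    active <- which(vapply(spec@planted, function(sig) {
      length(sig@conditions) == 0L || cond %in% sig@conditions
    }, logical(1)))
    for (mi in seq_along(spec@methods)) {
      method <- spec@methods[mi]
      seed <- .seedOffset(spec@seed, .STREAM_TABLES + 100L * ci + mi)
      tab <- withr::with_seed(seed, {
        t <- stats::rt(n, df = spec@df)
        lfc <- stats::rnorm(n, 0, spec@nullSigmaLfc)
        shift <- numeric(n)
        for (s in active) {
          sig <- spec@planted[[s]]
          idx <- geneIndex[responsive[[s]]]
          shift[idx] <- shift[idx] +
            ifelse(sig@direction == "up", 1, -1) * sig@delta
        }
        hit <- which(shift != 0)
        if (length(hit)) {
          t[hit] <- t[hit] + shift[hit]
          lfc[hit] <- sign(t[hit]) *
            abs(stats::rnorm(length(hit), abs(shift[hit]) * spec@nullSigmaLfc,
                             spec@nullSigmaLfc))
        }
        p <- 2 * stats::pt(-abs(t), df = spec@df)
        baseMean <- stats::rlnorm(n, meanlog = 5, sdlog = 1.5)
        data.frame(gene = genes, baseMean = baseMean, log2fc = lfc, stat = t,
                   p = p, padj = stats::p.adjust(p, method = "BH"),
                   stringsAsFactors = FALSE)
      })
      tables[[paste(cond, method, sep = ".")]] <- dgeTable(cond, method, tab)
    }
  }
  tables
}

#' Generate (and optionally write) a complete synthetic study bundle
#'
#' Runs [generateUniverse()], [generateCollection()] and
#' [generateDgeTables()] under one spec. With `outDir`, writes the bundle
#' in the interchange formats: `genesets.gmt`, `cofactor_annotation.tsv`,
#' one `dge_<condition>_<method>.tsv` per table (in the method's dialect)
#' and a `manifest.json` echoing the spec and the MD5 digest of every file.
#'
#' @param spec a [SimulationSpec-class].
#' @param outDir optional output directory (created if missing).
#' @return (invisibly) a list with `genes`, `annotation`, `collection`,
#'   `tables` and `spec`.
#' @examples
#' bundle <- simulateStudy(simulationSpec(nGenes = 300, nSets = 5,
#'                                        setSizeRange = c(5, 20), seed = 1))
#' names(bundle$tables)
#' @export
simulateStudy <- function(spec, outDir = NULL) {
  uni <- generateUniverse(spec)
  collection <- generateCollection(uni$genes, spec)
  tables <- generateDgeTables(uni$genes, collection, spec)
  bundle <- list(genes = uni$genes, annotation = uni$annotation,
                 collection = collection, tables = tables, spec = spec)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeGmt(collection, file.path(outDir, "genesets.gmt"))
    writeCofactorAnnotation(uni$annotation,
                            file.path(outDir, "cofactor_annotation.tsv"))
    for (tab in tables) {
      fn <- sprintf("dge_%s_%s.tsv", conditionLabel(tab), dgeMethod(tab))
      writeDgeTable(tab, file.path(outDir, fn))
    }
    files <- sort(list.files(outDir, full.names = TRUE))
    manifest <- list(
      generator = "cofgsea::simulateStudy",
      version = as.character(utils::packageVersion("cofgsea")),
      spec = .specAsList(spec),
      files = as.list(tools::md5sum(files))
    )
    names(manifest$files) <- basename(files)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(bundle)
}

.specAsList <- function(spec) {
  list(n_genes = spec@nGenes, n_sets = spec@nSets,
       set_size_range = spec@setSizeRange,
       cofactor_fraction = spec@cofactorFraction,
       n_conditions = spec@nConditions,
       condition_labels = spec@conditionLabels, methods = spec@methods,
       planted = lapply(spec@planted, function(sig) {
         list(target_set = sig@targetSet, direction = sig@direction,
              responsive_fraction = sig@responsiveFraction, delta = sig@delta,
              conditions = sig@conditions)
       }),
       null_sigma_lfc = spec@nullSigmaLfc, df = spec@df, seed = spec@seed)
}

.specFromList <- function(x) {
  planted <- lapply(x$planted %||% list(), function(s) {
    plantedSignal(s$target_set, s$direction,
                  s$responsive_fraction %||% 0.3, s$delta %||% 2,
                  unlist(s$conditions) %||% character(0))
  })
  labels <- unlist(x$condition_labels) %||%
    c("LF_fed", "LF_fasted", "HF_fed", "HF_fasted")
  simulationSpec(
    nGenes = x$n_genes %||% 10000, nSets = x$n_sets %||% 100,
    setSizeRange = unlist(x$set_size_range) %||% c(20, 150),
    cofactorFraction = unlist(x$cofactor_fraction) %||% 0.1,
    nConditions = x$n_conditions %||% length(labels),
    conditionLabels = labels,
    methods = unlist(x$methods) %||% c("deseq2", "voom"),
    planted = planted, nullSigmaLfc = x$null_sigma_lfc %||% 0.4,
    df = x$df %||% 10, seed = x$seed %||% 1)
}
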
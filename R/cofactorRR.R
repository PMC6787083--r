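#' Cofactor risk ratio over contributing genes
#'
#' Quantifies whether cofactor (CoA / NAD(P)(H)) genes are overrepresented
#' among the contributing (leading-edge) genes of a gene set:
#'
#' \deqn{RR = \frac{\#CG_{cof} / \#CG}{(\#genes_{cof} - \#CG_{cof}) /
#'   (\#genes - \#CG)}}
#'
#' where `#CG` is the number of contributing genes, `#CG_cof` the number of
#' those that are cofactor genes, `#genes` the set size and `#genes_cof`
#' the number of cofactor genes in the whole set. The formula is applied
#' exactly as stated, conditioning the denominator on the same set; no
#' 2x2-table correction is made. A value above 1 flags overrepresentation.
#' Degenerate cases: a zero numerator yields `rr = 0`; a zero denominator
#' with a positive numerator (every cofactor gene contributes) yields
#' `rr = Inf`, flagged as overrepresented. `nCg = 0` or `nGenes = nCg` is
#' an error (no contributing genes / empty non-contributing pool).
#'
#' All arguments are vectorized.
#'
#' @param nCg number of contributing genes in the set.
#' @param nCgCof contributing genes that are cofactor genes.
#' @param nGenes total genes in the set.
#' @param nGenesCof total cofactor genes in the set.
#' @return data.frame with columns `nCg`, `nCgCof`, `nGenes`, `nGenesCof`,
#'   `rr`, `overrepresented`.
#' @examples
#' cofactorRiskRatio(10, 4, 50, 10)$rr  # 2.6667: overrepresented
#' cofactorRiskRatio(10, 2, 50, 10)$rr  # exactly proportional: 1
#' @export
cofactorRiskRatio <- function(nCg, nCgCof, nGenes, nGenesCof) {
  n <- max(length(nCg), length(nCgCof), length(nGenes), length(nGenesCof))
  nCg <- rep_len(as.numeric(nCg), n)
  nCgCof <- rep_len(as.numeric(nCgCof), n)
  nGenes <- rep_len(as.numeric(nGenes), n)
  nGenesCof <- rep_len(as.numeric(nGenesCof), n)
  if (any(nCgCof < 0 | nCgCof > nCg | nCg > nGenes | nCgCof > nGenesCof |
          nGenesCof > nGenes)) {
    stop("counts must satisfy 0 <= nCgCof <= nCg <= nGenes and nCgCof <= nGenesCof <= nGenes")
  }
  if (any(nCg == 0)) stop("no contributing genes (nCg = 0): RR undefined")
  if (any(nGenes == nCg))
    stop("every set gene contributes (nGenes = nCg): RR undefined")
  num <- nCgCof / nCg
  den <- (nGenesCof - nCgCof) / (nGenes - nCg)
  rr <- ifelse(nCgCof == 0, 0, ifelse(den == 0, Inf, num / den))
  data.frame(nCg = nCg, nCgCof = nCgCof, nGenes = nGenes,
             nGenesCof = nGenesCof, rr = rr, overrepresented = rr > 1)
}

#' Cofactor risk ratios for enriched gene sets
#'
#' For every GSEA result below the FDR threshold (default: the explorative
#' tier, FDR < 0.25), tallies the four counts of [cofactorRiskRatio()] from
#' the set's members, its leading edge and the cofactor annotation, and
#' evaluates the risk ratio. "Cofactor genes" pools the CoA and
#' NAD(P)(H)-main flags by default (`nadphClass = "main"`); the stricter
#' redox definition is available via `nadphClass = "redox"`. Set members
#' absent from the annotation are treated as non-cofactor genes (logged).
#' Per-class risk ratios (CoA alone, NAD(P)(H) alone) and a two-sided
#' Fisher exact p-value on the corresponding 2x2 table are emitted as
#' supplementary, purely informational columns — the overrepresentation
#' call itself uses only the `rr > 1` rule.
#'
#' @param results data.frame from [runPreranked()].
#' @param collection the [GeneSetCollection-class] the results refer to.
#' @param annotation a [CofactorAnnotation-class].
#' @param fdrThreshold keep sets with `fdrQ` strictly below this value.
#' @param nadphClass `"main"` (default) or `"redox"`.
#' @return data.frame with one row per retained set: identification,
#'   counts, `rr`, `overrepresented`, `rrCoa`, `rrNadph`, `fisherP`.
#' @export
annotateResultsWithRr <- function(results, collection, annotation,
                                  fdrThreshold = 0.25,
                                  nadphClass = c("main", "redox")) {
  stopifnot(is(collection, "GeneSetCollection"),
            is(annotation, "CofactorAnnotation"))
  nadphClass <- match.arg(nadphClass)
  nadph <- if (nadphClass == "main") "nadph_main" else "nadph_redox"
  keep <- !is.na(results$fdrQ) & results$fdrQ < fdrThreshold
  res <- results[keep, , drop = FALSE]
  if (!nrow(res)) {
    return(data.frame(setName = character(0), direction = character(0),
                      fdrQ = numeric(0), nCg = integer(0), nCgCof = integer(0),
                      nGenes = integer(0), nGenesCof = integer(0),
                      rr = numeric(0), overrepresented = logical(0),
                      rrCoa = numeric(0), rrNadph = numeric(0),
                      fisherP = numeric(0), stringsAsFactors = FALSE))
  }
  sets <- geneSets(collection)
  missing <- setdiff(unique(unlist(sets[res$setName])), annotation@gene)
  if (length(missing)) {
    message(sprintf(paste0("annotateResultsWithRr: %d set member(s) missing ",
                           "from the annotation; treated as non-cofactor"),
                    length(missing)))
  }
  classGenes <- list(pooled = cofactorGenes(annotation, c("coa", nadph)),
                     coa = cofactorGenes(annotation, "coa"),
                     nadph = cofactorGenes(annotation, nadph))
  rows <- lapply(seq_len(nrow(res)), function(i) {
    members <- sets[[res$setName[i]]]
    le <- res$leadingEdge[[i]]
    counts <- function(cof) {
      c(nCg = length(le), nCgCof = length(intersect(le, cof)),
        nGenes = length(members), nGenesCof = length(intersect(members, cof)))
    }
    cn <- counts(classGenes$pooled)
    # a leading edge that is empty or spans the whole set leaves the ratio
    # undefined; keep the row with NA rather than aborting the report
    degenerate <- cn["nCg"] == 0 || cn["nCg"] == cn["nGenes"]
    if (degenerate) {
      message(sprintf(paste0("annotateResultsWithRr: risk ratio undefined for ",
                             "set '%s' (contributing genes: %d of %d)"),
                      res$setName[i], cn["nCg"], cn["nGenes"]))
    }
    rr <- if (degenerate) {
      data.frame(rr = NA_real_, overrepresented = NA)
    } else {
      cofactorRiskRatio(cn["nCg"], cn["nCgCof"], cn["nGenes"],
                        cn["nGenesCof"])
    }
    crrOf <- function(cof) {
      if (degenerate) return(NA_real_)
      x <- counts(cof)
      cofactorRiskRatio(x["nCg"], x["nCgCof"], x["nGenes"], x["nGenesCof"])$rr
    }
    tab <- matrix(c(cn["nCgCof"], cn["nCg"] - cn["nCgCof"],
                    cn["nGenesCof"] - cn["nCgCof"],
                    (cn["nGenes"] - cn["nCg"]) -
                      (cn["nGenesCof"] - cn["nCgCof"])), 2)
    data.frame(setName = res$setName[i], direction = res$direction[i],
               fdrQ = res$fdrQ[i], nCg = unname(cn["nCg"]),
               nCgCof = unname(cn["nCgCof"]), nGenes = unname(cn["nGenes"]),
               nGenesCof = unname(cn["nGenesCof"]), rr = rr$rr,
               overrepresented = rr$overrepresented,
               rrCoa = crrOf(classGenes$coa), rrNadph = crrOf(classGenes$nadph),
               fisherP = stats::fisher.test(tab)$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
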
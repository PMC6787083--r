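#' Count DE genes inside each gene set
#'
#' The DE list is first intersected with the collection's universe (the
#' "metabolic genes"), so the shared denominator counts metabolic DE genes
#' only; genes outside the universe are dropped with a logged count.
#'
#' @param deGenes character vector of differentially expressed genes (one
#'   condition, one direction).
#' @param collection a [GeneSetCollection-class].
#' @return data.frame with columns `setName`, `nDegInSet`, `nDegAll`,
#'   `nSet`, `nMetabolic`.
#' @export
countDeInSets <- function(deGenes, collection) {
  stopifnot(is(collection, "GeneSetCollection"))
  uni <- universe(collection)
  deGenes <- unique(deGenes)
  deg <- deGenes[deGenes %in% uni]
  dropped <- length(deGenes) - length(deg)
  if (dropped > 0) {
    message(sprintf("countDeInSets: %d DE gene(s) outside the universe dropped",
                    dropped))
  }
  sets <- geneSets(collection)
  data.frame(setName = names(sets),
             nDegInSet = vapply(sets, function(m) sum(deg %in% m), integer(1)),
             nDegAll = length(deg), nSet = lengths(sets),
             nMetabolic = length(uni), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Percentage of DE genes per set, with the tie- and zero-rank rules
#'
#' The percentage is `100 * nDegInSet / nDegAll` (0 when `nDegAll` is 0, in
#' which case the whole condition x direction is marked degenerate). Sets
#' are ranked by decreasing percentage. Tied percentages share a rank —
#' competition (minimum) rank by default, dense ranking via
#' `tieMethod = "dense"` — and every zero-percentage set receives the rank
#' equal to the number of sets in the collection.
#'
#' @param counts data.frame from [countDeInSets()].
#' @param tieMethod `"competition"` (default) or `"dense"`.
#' @return the input with added columns `percentage`, `rank`, `degenerate`.
#' @examples
#' counts <- data.frame(setName = paste0("S", 1:5),
#'                      nDegInSet = c(5, 3, 3, 0, 0), nDegAll = 10,
#'                      nSet = 10, nMetabolic = 100)
#' percentageAndRank(counts)$rank  # 1 2 2 5 5
#' @export
percentageAndRank <- function(counts, tieMethod = c("competition", "dense")) {
  tieMethod <- match.arg(tieMethod)
  nSets <- nrow(counts)
  degenerate <- counts$nDegAll == 0
  pct <- ifelse(degenerate, 0, 100 * counts$nDegInSet / counts$nDegAll)
  rk <- if (tieMethod == "competition") {
    rank(-pct, ties.method = "min")
  } else {
    match(-pct, sort(unique(-pct)))
  }
  rk[pct == 0] <- nSets
  out <- counts
  out$percentage <- pct
  out$rank <- as.integer(rk)
  out$degenerate <- degenerate
  out
}

#' Risk ratio of a gene set among the DE genes
#'
#' \deqn{RR = \frac{\#DEG_{set} / \#DEG_{all}}{(\#genes_{set} -
#'   \#DEG_{set}) / (\#metabolic - \#DEG_{all})}}
#'
#' evaluated exactly as stated, with `rr > 1` flagging overrepresentation.
#' Degenerate cases: `nDegInSet = 0` gives `rr = 0`; a whole set
#' differentially expressed (`nDegInSet = nSet`) gives `rr = Inf`, flagged;
#' `nDegAll = 0` leaves the cell undefined (`NA`, not overrepresented);
#' `nMetabolic = nDegAll` is an error. Vectorized.
#'
#' @param nDegInSet DE genes inside the set.
#' @param nDegAll DE genes in the whole (metabolic) universe.
#' @param nSet set size.
#' @param nMetabolic universe size.
#' @return data.frame with columns `rr` and `overrepresented`.
#' @examples
#' rrGeneset(10, 100, 50, 1000)$rr  # 2.25
#' @export
rrGeneset <- function(nDegInSet, nDegAll, nSet, nMetabolic) {
  n <- max(length(nDegInSet), length(nDegAll), length(nSet),
           length(nMetabolic))
  nDegInSet <- rep_len(as.numeric(nDegInSet), n)
  nDegAll <- rep_len(as.numeric(nDegAll), n)
  nSet <- rep_len(as.numeric(nSet), n)
  nMetabolic <- rep_len(as.numeric(nMetabolic), n)
  if (any(nDegInSet < 0 | nDegInSet > pmin(nDegAll, nSet) | nSet > nMetabolic))
    stop("counts must satisfy 0 <= nDegInSet <= min(nDegAll, nSet) and nSet <= nMetabolic")
  if (any(nMetabolic == nDegAll & nDegAll > 0))
    stop("every metabolic gene is differentially expressed: RR undefined")
  num <- nDegInSet / nDegAll
  den <- (nSet - nDegInSet) / (nMetabolic - nDegAll)
  rr <- ifelse(nDegAll == 0, NA_real_,
               ifelse(nDegInSet == 0, 0, ifelse(den == 0, Inf, num / den)))
  data.frame(rr = rr, overrepresented = !is.na(rr) & rr > 1)
}

#' Per-condition, per-direction alternative enrichment cells
#'
#' For every (condition x direction) pair, computes the DE counts,
#' percentage, rank and risk ratio of every set in the collection. A pair
#' absent from `deLists` (no DE genes) yields degenerate cells with rank
#' equal to the number of sets.
#'
#' @param deLists data.frame with columns `condition`, `direction`, `gene`
#'   (e.g. from [buildDeGeneLists()]).
#' @param collection a [GeneSetCollection-class].
#' @param conditions conditions to analyse; defaults to those present in
#'   `deLists`.
#' @param tieMethod passed to [percentageAndRank()].
#' @return data.frame of cells: `setName`, `condition`, `direction`, the
#'   four counts, `percentage`, `rank`, `degenerate`, `rr`,
#'   `overrepresented`.
#' @export
runAltGsea <- function(deLists, collection, conditions = NULL,
                       tieMethod = "competition") {
  stopifnot(is(collection, "GeneSetCollection"))
  conditions <- conditions %||% unique(deLists$condition)
  if (!length(conditions)) stop("no conditions to analyse")
  grid <- expand.grid(condition = conditions, direction = c("up", "down"),
                      stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    genes <- deLists$gene[deLists$condition == grid$condition[i] &
                            deLists$direction == grid$direction[i]]
    pr <- percentageAndRank(countDeInSets(genes, collection),
                            tieMethod = tieMethod)
    rr <- rrGeneset(pr$nDegInSet, pr$nDegAll, pr$nSet, pr$nMetabolic)
    cbind(pr[, "setName", drop = FALSE], condition = grid$condition[i],
          direction = grid$direction[i],
          pr[, c("nDegInSet", "nDegAll", "nSet", "nMetabolic", "percentage",
                 "rank", "degenerate")], rr)
  })
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}

#' Aggregate per-condition ranks by the median
#'
#' For each (set x direction), the overall rank is the competition rank of
#' the median of the per-condition ranks (an even number of conditions
#' averages the two middle values), with ties in the overall ordering
#' broken by set name for determinism. Overrepresentation is counted across
#' conditions and `multiConditionFlag` marks sets overrepresented in two or
#' more conditions in that direction. A set missing a rank in any condition
#' is an error.
#'
#' @param cells data.frame from [runAltGsea()].
#' @return data.frame with one row per (set x direction): `setName`,
#'   `direction`, one `rank_<condition>` column per condition,
#'   `medianRank`, `overallRank`, `nConditionsOverrepresented`,
#'   `multiConditionFlag`, ordered by direction then overall rank.
#' @export
aggregateMedianRank <- function(cells) {
  conds <- unique(cells$condition)
  out <- lapply(split(cells, cells$direction), function(sub) {
    bySet <- split(sub, sub$setName)
    bad <- names(bySet)[vapply(bySet, function(s)
      !setequal(s$condition, conds) || nrow(s) != length(conds), logical(1))]
    if (length(bad)) {
      stop(sprintf("set(s) missing a rank in some condition: %s",
                   paste(bad, collapse = ", ")))
    }
    rows <- lapply(bySet, function(s) {
      s <- s[match(conds, s$condition), , drop = FALSE]
      rk <- as.list(s$rank)
      names(rk) <- paste0("rank_", conds)
      cbind(data.frame(setName = s$setName[1], direction = s$direction[1],
                       stringsAsFactors = FALSE),
            as.data.frame(rk),
            data.frame(medianRank = stats::median(s$rank),
                       nConditionsOverrepresented = sum(s$overrepresented),
                       stringsAsFactors = FALSE))
    })
    agg <- do.call(rbind, rows)
    agg$overallRank <- as.integer(rank(agg$medianRank, ties.method = "min"))
    agg$multiConditionFlag <- agg$nConditionsOverrepresented >= 2L
    agg[order(agg$overallRank, agg$setName), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Top-k table of the alternative enrichment analysis
#'
#' Returns, per direction, the `k` sets with the smallest overall (median)
#' rank, annotated with the multi-condition overrepresentation flag and —
#' when a tiered GSEA report is supplied — the classical-GSEA FDR tier of
#' the same set and direction, mirroring the bold/asterisk marks of a
#' published top-10 table. If `k` exceeds the number of sets the full list
#' is returned with a notice.
#'
#' @param summaries data.frame from [aggregateMedianRank()].
#' @param k sets per direction (default 10).
#' @param gseaReport optional data.frame from [reportGsea()] (may pool
#'   several conditions).
#' @return data.frame of the selected rows, plus a `gseaTier` column when
#'   `gseaReport` is given.
#' @export
altGseaTopTable <- function(summaries, k = 10, gseaReport = NULL) {
  out <- lapply(split(summaries, summaries$direction), function(sub) {
    sub <- sub[order(sub$overallRank, sub$setName), , drop = FALSE]
    if (k > nrow(sub)) {
      message(sprintf("altGseaTopTable: k = %d exceeds %d set(s); returning all",
                      k, nrow(sub)))
    }
    utils::head(sub, k)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!is.null(gseaReport) && nrow(out)) {
    # a set may be reported for several conditions: keep the best tier
    gr <- gseaReport[order(gseaReport$tier != "significant"), , drop = FALSE]
    key <- paste(out$setName, out$direction)
    gkey <- paste(gr$setName, gr$direction)
    idx <- match(key, gkey)
    out$gseaTier <- ifelse(is.na(idx), "", gr$tier[idx])
  }
  out
}
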
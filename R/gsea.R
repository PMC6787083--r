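#' Weighted running-sum enrichment score
#'
#' Walks down the ranked list accumulating `|score|^w / sum(|score|^w over
#' members)` at member positions and `-1 / (N - nMembers)` elsewhere. The
#' enrichment score (ES) is the running-sum value of maximal absolute
#' deviation from zero; on an exact tie between the positive and negative
#' extremum the positive one is reported. The leading edge ("contributing
#' genes") is the member subset at or before the ES-attaining position for
#' a positive ES, and at or after it for a negative ES.
#'
#' If every member's weight is zero (all member scores exactly 0 under
#' `weightExponent > 0`), members are weighted equally.
#'
#' @param ranked named numeric vector sorted in decreasing order (see
#'   [makeRankedList()]).
#' @param members character vector of gene symbols.
#' @param weightExponent exponent on the absolute score (1 = weighted
#'   statistic, 0 = classic Kolmogorov-Smirnov form).
#' @return list with `es`, `runningSum` (length `N`) and `leadingEdge`
#'   (genes in rank order).
#' @examples
#' ranked <- c(a = 4, b = 3, c = 2, d = 1)
#' enrichmentScore(ranked, c("a", "c"))$es  # 2/3
#' @export
enrichmentScore <- function(ranked, members, weightExponent = 1) {
  if (is.null(names(ranked)) || is.unsorted(rev(ranked)))
    stop("'ranked' must be a named numeric vector in decreasing order")
  N <- length(ranked)
  hit <- names(ranked) %in% members
  k <- sum(hit)
  if (k == 0L) stop("no gene set member present in the ranked list")
  if (k == N) stop("gene set spans the entire ranked list (miss pool empty)")
  w <- abs(ranked)^weightExponent
  sumw <- sum(w[hit])
  incr <- rep.int(-1 / (N - k), N)
  incr[hit] <- if (sumw == 0) 1 / k else w[hit] / sumw
  running <- cumsum(incr)
  iMax <- which.max(running)
  iMin <- which.min(running)
  # positive extremum wins on a tie; the comparison carries a small
  # tolerance so that mathematically exact ties are not decided by
  # floating-point accumulation noise
  es <- if (running[iMax] >= -running[iMin] - 1e-12) running[iMax]
        else running[iMin]
  lePos <- if (es >= 0) which(hit & seq_len(N) <= iMax)
           else which(hit & seq_len(N) >= iMin)
  list(es = es, runningSum = running, leadingEdge = names(ranked)[lePos])
}

## Vectorized ES over many same-size position sets (columns of posMat, each
## sorted ascending). Exploits piecewise linearity: between hits the running
## sum decreases linearly, so the maximum is attained just after a hit and
## the minimum just before one (or at the boundary value 0).
.esBatch <- function(posMat, absScoresW, N) {
  k <- nrow(posMat)
  m <- ncol(posMat)
  W <- matrix(absScoresW[posMat], k, m)
  cs <- cumsum(as.vector(W))
  colEnd <- cs[k * seq_len(m)]
  prevEnd <- c(0, colEnd[-m])
  hitCum <- matrix(cs - rep(prevEnd, each = k), k, m)
  sumW <- colEnd - prevEnd
  zero <- sumW == 0
  if (any(zero)) {  # all-zero member weights: fall back to equal weighting
    W[, zero] <- 1
    hitCum[, zero] <- matrix(rep(seq_len(k), sum(zero)), k)
    sumW[zero] <- k
  }
  sumWm <- rep(sumW, each = k)
  missTerm <- (posMat - seq_len(k)) / (N - k)
  after <- hitCum / sumWm - missTerm
  before <- after - W / sumWm
  maxAfter <- as.vector(do.call(pmax, c(asplit(after, 1), list(rep(-Inf, m)))))
  minBefore <- pmin(as.vector(do.call(pmin, c(asplit(before, 1),
                                              list(rep(Inf, m))))), 0)
  ifelse(maxAfter >= -minBefore - 1e-12, maxAfter, minBefore)
}

#' Pre-ranked gene set enrichment with a gene-set permutation null
#'
#' For each gene set (restricted to the ranked universe and filtered by the
#' size window), the observed [enrichmentScore()] is compared against the
#' ES distribution of `nPermutations` random same-size gene sets drawn from
#' the ranked universe. The nominal p-value is the one-sided tail frequency
#' among null scores of the matching sign, smoothed by `+1/(n+1)` so it is
#' never exactly zero. NES is the observed ES divided by the mean absolute
#' null ES of the matching sign. The FDR q-value follows the standard
#' permutation recipe: the tail fraction of the pooled sign-normalized null
#' NES relative to the tail fraction of the observed NES, clipped to
#' `[0, 1]` and made monotone in |NES|.
#'
#' @param ranked named numeric vector in decreasing order.
#' @param collection a [GeneSetCollection-class].
#' @param config a [GseaConfig-class].
#' @return data.frame with one row per analysed set: `setName`, `size`,
#'   `es`, `nes`, `pNominal`, `fdrQ`, `direction` (`"up"` for positive ES),
#'   `leadingEdgeSize` and `leadingEdge` (list column of gene vectors).
#' @export
runPreranked <- function(ranked, collection, config = gseaConfig()) {
  stopifnot(is(collection, "GeneSetCollection"), is(config, "GseaConfig"))
  validObject(config)
  N <- length(ranked)
  sets <- lapply(geneSets(collection), function(m) m[m %in% names(ranked)])
  sizes <- lengths(sets)
  skipped <- names(sets)[sizes == 0L]
  if (length(skipped)) {
    warning(sprintf("skipping set(s) with no member in the ranked list: %s",
                    paste(skipped, collapse = ", ")))
  }
  keep <- sizes >= max(1, config@minSetSize) & sizes <= config@maxSetSize &
    sizes < N
  sets <- sets[keep]
  sizes <- sizes[keep]
  if (!length(sets)) stop("no gene set left after size filtering")

  absW <- abs(ranked)^config@weightExponent
  nperm <- config@nPermutations
  obs <- lapply(sets, function(m) enrichmentScore(ranked, m,
                                                  config@weightExponent))
  es <- vapply(obs, `[[`, numeric(1), "es")

  nes <- rep(NA_real_, length(sets))
  pNominal <- rep(NA_real_, length(sets))
  nullNes <- vector("list", length(sets))
  withr::with_seed(config@seed, {
    for (i in seq_along(sets)) {
      k <- sizes[i]
      posMat <- vapply(seq_len(nperm),
                       function(j) sort.int(sample.int(N, k)), integer(k))
      if (k == 1L) posMat <- matrix(posMat, nrow = 1L)
      nullEs <- .esBatch(posMat, absW, N)
      pos <- nullEs[nullEs >= 0]
      neg <- nullEs[nullEs < 0]
      meanPos <- if (length(pos)) mean(pos) else NA_real_
      meanNeg <- if (length(neg)) mean(abs(neg)) else NA_real_
      if (es[i] >= 0) {
        pNominal[i] <- (1 + sum(pos >= es[i])) / (1 + length(pos))
        nes[i] <- if (!is.na(meanPos) && meanPos > 0) es[i] / meanPos
                  else NA_real_
      } else {
        pNominal[i] <- (1 + sum(neg <= es[i])) / (1 + length(neg))
        nes[i] <- if (!is.na(meanNeg) && meanNeg > 0) es[i] / meanNeg
                  else NA_real_
      }
      norm <- nullEs
      if (!is.na(meanPos) && meanPos > 0)
        norm[nullEs >= 0] <- nullEs[nullEs >= 0] / meanPos
      if (!is.na(meanNeg) && meanNeg > 0)
        norm[nullEs < 0] <- nullEs[nullEs < 0] / meanNeg
      nullNes[[i]] <- norm
    }
  })

  fdrQ <- .permutationFdr(nes, unlist(nullNes, use.names = FALSE))
  data.frame(setName = names(sets), size = as.integer(sizes), es = es,
             nes = nes, pNominal = pNominal, fdrQ = fdrQ,
             direction = ifelse(es >= 0, "up", "down"),
             leadingEdgeSize = vapply(obs, function(o) length(o$leadingEdge),
                                      integer(1)),
             leadingEdge = I(lapply(obs, `[[`, "leadingEdge")),
             stringsAsFactors = FALSE, row.names = NULL)
}

## FDR q per the permutation recipe: ratio of null vs observed tail
## fractions on the matching sign, clipped, then monotonized so a more
## extreme NES never has a larger q than a less extreme one.
.permutationFdr <- function(nes, pooledNull) {
  q <- rep(NA_real_, length(nes))
  posNull <- pooledNull[!is.na(pooledNull) & pooledNull >= 0]
  negNull <- pooledNull[!is.na(pooledNull) & pooledNull < 0]
  obsPos <- which(!is.na(nes) & nes >= 0)
  obsNeg <- which(!is.na(nes) & nes < 0)
  if (length(obsPos) && length(posNull)) {
    num <- vapply(nes[obsPos], function(x) mean(posNull >= x), numeric(1))
    den <- vapply(nes[obsPos], function(x) mean(nes[obsPos] >= x), numeric(1))
    q[obsPos] <- pmin(1, num / den)
    ord <- obsPos[order(nes[obsPos])]  # ascending: least extreme first
    q[ord] <- cummin(q[ord])
  }
  if (length(obsNeg) && length(negNull)) {
    num <- vapply(nes[obsNeg], function(x) mean(negNull <= x), numeric(1))
    den <- vapply(nes[obsNeg], function(x) mean(nes[obsNeg] <= x), numeric(1))
    q[obsNeg] <- pmin(1, num / den)
    ord <- obsNeg[order(nes[obsNeg], decreasing = TRUE)]
    q[ord] <- cummin(q[ord])
  }
  q
}

#' Tiered enrichment report
#'
#' Splits results into the two reporting tiers per direction: FDR < the
#' significant threshold (default 0.05) and FDR in [significant,
#' explorative) (default [0.05, 0.25)); everything at or above the
#' explorative threshold is omitted. Within a direction, rows are ordered
#' by decreasing |NES|.
#'
#' @param results data.frame from [runPreranked()].
#' @param config a [GseaConfig-class] supplying the two thresholds.
#' @return data.frame with an added `tier` column
#'   (`"significant"`/`"explorative"`).
#' @export
reportGsea <- function(results, config = gseaConfig()) {
  stopifnot(is(config, "GseaConfig"))
  keep <- !is.na(results$fdrQ) & results$fdrQ < config@fdrExplorative
  out <- results[keep, , drop = FALSE]
  if (!nrow(out)) {
    out$tier <- character(0)
    return(out)
  }
  out$tier <- ifelse(out$fdrQ < config@fdrSignificant, "significant",
                     "explorative")
  out <- out[order(out$direction, -abs(out$nes)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write GSEA results as TSV
#'
#' One row per set with the leading-edge genes semicolon-joined.
#'
#' @param results data.frame from [runPreranked()] or [reportGsea()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGseaResults <- function(results, path) {
  out <- results
  out$leadingEdge <- vapply(results$leadingEdge, paste, character(1),
                            collapse = ";")
  .writeTsv(out, path)
}

#' Read GSEA results written by [writeGseaResults()]
#' @param path path to the TSV.
#' @return data.frame with `leadingEdge` restored as a list column.
#' @export
readGseaResults <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$leadingEdge <- I(lapply(strsplit(df$leadingEdge, ";", fixed = TRUE),
                             function(x) x[nzchar(x)]))
  df
}
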
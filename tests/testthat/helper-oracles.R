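# Independent reference implementations used as oracles. These deliberately
# use naive loops / different arithmetic than the package code paths.

# position-by-position running-sum ES oracle
esOracle <- function(scores, hitIdx, w = 1) {
  N <- length(scores)
  hits <- seq_len(N) %in% hitIdx
  sumw <- sum(abs(scores[hits])^w)
  run <- 0
  path <- numeric(N)
  for (i in seq_len(N)) {
    run <- run + if (hits[i]) {
      if (sumw == 0) 1 / sum(hits) else abs(scores[i])^w / sumw
    } else {
      -1 / (N - sum(hits))
    }
    path[i] <- run
  }
  hi <- max(path)
  lo <- min(path)
  # positive extremum wins on a (tolerance-guarded) tie, as in the package
  if (hi >= -lo - 1e-12) hi else lo
}

# brute-force truth table of the dual DE inclusion criteria
deCriteriaOracle <- function(lfc, p) {
  if (is.na(lfc) || is.na(p)) return(FALSE)
  clauseA <- (abs(lfc) > 0.5) && (p < 0.1)
  clauseB <- p < 0.05
  clauseA || clauseB
}

# loop-tally + integer cross-multiplication oracle for the cofactor RR:
# builds explicit gene lists, counts by looping, and evaluates the ratio
# via integer products to avoid sharing the division path
cofactorRrOracle <- function(nCg, nCgCof, nGenes, nGenesCof) {
  genes <- seq_len(nGenes)
  contributing <- genes <= nCg
  # cofactor genes: the first nCgCof contributing plus enough non-contributing
  cof <- logical(nGenes)
  cof[seq_len(nCgCof)] <- TRUE
  extra <- nGenesCof - nCgCof
  if (extra > 0) cof[nCg + seq_len(extra)] <- TRUE
  a <- 0; b <- 0; cC <- 0; d <- 0
  for (g in genes) {
    if (contributing[g] && cof[g]) a <- a + 1
    if (contributing[g]) b <- b + 1
    if (cof[g]) cC <- cC + 1
    d <- d + 1
  }
  num <- a * (d - b)
  den <- b * (cC - a)
  if (a == 0) 0 else if (den == 0) Inf else num / den
}

rrGenesetOracle <- function(nDegInSet, nDegAll, nSet, nMetabolic) {
  if (nDegAll == 0) return(NA_real_)
  num <- nDegInSet * (nMetabolic - nDegAll)
  den <- nDegAll * (nSet - nDegInSet)
  if (nDegInSet == 0) 0 else if (den == 0) Inf else num / den
}

# nested-loop reference for the whole alternative-enrichment computation
altGseaOracle <- function(deByCondDir, sets, tieZeroRank = TRUE) {
  uni <- sort(unique(unlist(sets)))
  nSets <- length(sets)
  cells <- list()
  for (cond in names(deByCondDir)) {
    for (dir in names(deByCondDir[[cond]])) {
      de <- intersect(deByCondDir[[cond]][[dir]], uni)
      counts <- integer(nSets)
      for (i in seq_len(nSets)) {
        for (g in de) if (g %in% sets[[i]]) counts[i] <- counts[i] + 1
      }
      pct <- if (length(de)) 100 * counts / length(de) else rep(0, nSets)
      rk <- integer(nSets)
      for (i in seq_len(nSets)) {
        rk[i] <- if (pct[i] == 0) nSets else 1 + sum(pct > pct[i])
      }
      rr <- vapply(seq_len(nSets), function(i) {
        rrGenesetOracle(counts[i], length(de), length(sets[[i]]), length(uni))
      }, numeric(1))
      cells[[paste(cond, dir)]] <- data.frame(
        setName = names(sets), condition = cond, direction = dir,
        nDegInSet = counts, nDegAll = length(de), percentage = pct,
        rank = rk, rr = rr, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, cells)
}
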
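test_that("DE genes are counted inside sets against the metabolic universe", {
  gsc <- geneSetCollection(list(S = c("A", "C"), T = c("A", "B", "C", "D")))
  expect_message(counts <- countDeInSets(c("A", "B", "X"), gsc), "outside")
  expect_equal(counts$nDegInSet[counts$setName == "S"], 1L)
  expect_equal(unique(counts$nDegAll), 2L)
  expect_equal(unique(counts$nMetabolic), 4L)
  empty <- countDeInSets(character(0), gsc)
  expect_true(all(empty$nDegInSet == 0L) && all(empty$nDegAll == 0L))
})

test_that("percentage ranking applies the tie rule and the zero rule", {
  counts <- data.frame(setName = paste0("S", 1:5),
                       nDegInSet = c(5, 3, 3, 0, 0), nDegAll = 10,
                       nSet = 10, nMetabolic = 100)
  pr <- percentageAndRank(counts)
  expect_equal(pr$percentage, c(50, 30, 30, 0, 0))
  expect_identical(pr$rank, c(1L, 2L, 2L, 5L, 5L))
  # all-zero percentages: every rank equals the number of sets
  zero <- counts; zero$nDegInSet <- 0
  expect_true(all(percentageAndRank(zero)$rank == 5L))
  # degenerate condition: no DE genes at all
  deg <- counts; deg$nDegAll <- 0; deg$nDegInSet <- 0
  prd <- percentageAndRank(deg)
  expect_true(all(prd$degenerate) && all(prd$rank == 5L))
  # all distinct: ranks are 1..n_nonzero plus n for zeros
  dist <- data.frame(setName = paste0("S", 1:4),
                     nDegInSet = c(4, 3, 1, 0), nDegAll = 10, nSet = 10,
                     nMetabolic = 100)
  expect_identical(percentageAndRank(dist)$rank, c(1L, 2L, 3L, 4L))
  # dense ranking variant shares consecutive ranks
  expect_identical(percentageAndRank(counts, tieMethod = "dense")$rank,
                   c(1L, 2L, 2L, 5L, 5L))
})

test_that("gene-set risk ratio reproduces the printed-formula examples", {
  expect_equal(rrGeneset(5, 100, 50, 1000)$rr, 1)
  expect_false(rrGeneset(5, 100, 50, 1000)$overrepresented)
  expect_equal(rrGeneset(10, 100, 50, 1000)$rr, 2.25, tolerance = 1e-12)
  expect_true(rrGeneset(10, 100, 50, 1000)$overrepresented)
  whole <- rrGeneset(50, 100, 50, 1000)
  expect_identical(whole$rr, Inf)
  expect_true(whole$overrepresented)
  expect_identical(rrGeneset(0, 100, 50, 1000)$rr, 0)
  degenerate <- rrGeneset(0, 0, 50, 1000)
  expect_true(is.na(degenerate$rr))
  expect_false(degenerate$overrepresented)
  expect_error(rrGeneset(10, 100, 50, 100), "undefined")
  expect_error(rrGeneset(60, 100, 50, 1000), "counts must satisfy")
})

test_that("gene-set RR matches the cross-multiplication oracle", {
  withr::with_seed(555, {
    for (i in 1:400) {
      nMetabolic <- sample(20:2000, 1)
      nDegAll <- sample(0:(nMetabolic - 1), 1)
      nSet <- sample(1:min(nMetabolic, 300), 1)
      nDegInSet <- sample(0:min(nDegAll, nSet), 1)
      got <- rrGeneset(nDegInSet, nDegAll, nSet, nMetabolic)
      want <- rrGenesetOracle(nDegInSet, nDegAll, nSet, nMetabolic)
      expect_equal(got$rr, want, tolerance = 1e-12)
    }
  })
})

test_that("the whole alternative analysis matches a nested-loop reference", {
  withr::with_seed(77, {
    for (rep in 1:5) {
      nGenes <- sample(50:200, 1)
      genes <- sprintf("g%03d", seq_len(nGenes))
      nSets <- sample(5:20, 1)
      sets <- lapply(seq_len(nSets), function(i)
        sample(genes, sample(3:20, 1)))
      names(sets) <- sprintf("S%02d", seq_len(nSets))
      conds <- c("c1", "c2", "c3")
      deLists <- do.call(rbind, lapply(conds, function(cond) {
        do.call(rbind, lapply(c("up", "down"), function(dir) {
          k <- sample(0:15, 1)
          if (!k) return(NULL)
          data.frame(condition = cond, direction = dir,
                     gene = sample(genes, k), stringsAsFactors = FALSE)
        }))
      }))
      gsc <- geneSetCollection(sets)
      cells <- suppressMessages(runAltGsea(deLists, gsc, conditions = conds))
      deByCondDir <- lapply(conds, function(cond) {
        list(up = deLists$gene[deLists$condition == cond &
                                 deLists$direction == "up"],
             down = deLists$gene[deLists$condition == cond &
                                   deLists$direction == "down"])
      })
      names(deByCondDir) <- conds
      ref <- altGseaOracle(deByCondDir, sets)
      key <- function(df) paste(df$setName, df$condition, df$direction)
      idx <- match(key(cells), key(ref))
      expect_false(anyNA(idx))
      expect_equal(cells$nDegInSet, ref$nDegInSet[idx])
      expect_equal(cells$percentage, ref$percentage[idx], tolerance = 1e-12)
      expect_equal(cells$rank, ref$rank[idx])
      expect_equal(cells$rr, ref$rr[idx], tolerance = 1e-12)
    }
  })
})

test_that("median aggregation uses the even-count convention and flags", {
  cells <- expand.grid(setName = c("A", "B"), condition = paste0("c", 1:4),
                       direction = "up", stringsAsFactors = FALSE)
  cells$rank <- c(2, 1, 7, 1, 90, 1, 90, 1)  # A: 2,7,90,90 ; B: 1,1,1,1
  cells$rr <- c(2, 0.5, 2, 0.5, 0.2, 0.5, 0.2, 2)  # A twice > 1, B once
  cells$overrepresented <- cells$rr > 1
  agg <- aggregateMedianRank(cells)
  a <- agg[agg$setName == "A", ]
  b <- agg[agg$setName == "B", ]
  expect_equal(a$medianRank, 48.5)
  expect_equal(b$medianRank, 1)
  expect_identical(b$overallRank, 1L)
  expect_identical(a$overallRank, 2L)
  expect_identical(a$nConditionsOverrepresented, 2L)
  expect_true(a$multiConditionFlag)
  expect_false(b$multiConditionFlag)
  expect_true(all(agg$medianRank >= pmin(2, 1) & agg$medianRank <= 90))
  # a set missing a condition is an error
  expect_error(aggregateMedianRank(cells[-1, ]), "missing a rank")
})

test_that("adding a DE gene of a set never worsens that set's rank", {
  withr::with_seed(31, {
    genes <- sprintf("g%03d", 1:100)
    sets <- list(S1 = sample(genes, 20), S2 = sample(genes, 20),
                 S3 = sample(genes, 20))
    gsc <- geneSetCollection(sets)
    de <- sample(universe(gsc), 15)
  })
  rank0 <- percentageAndRank(countDeInSets(de, gsc))
  extra <- setdiff(sets$S1, de)[1]
  rank1 <- percentageAndRank(countDeInSets(c(de, extra), gsc))
  expect_lte(rank1$rank[rank1$setName == "S1"],
             rank0$rank[rank0$setName == "S1"])
})

test_that("top table selects by overall rank and cross-references GSEA tiers", {
  summaries <- data.frame(
    setName = c("A", "B", "C", "D"), direction = "up",
    medianRank = c(1, 2, 3, 4), overallRank = 1:4,
    nConditionsOverrepresented = c(3L, 2L, 1L, 0L),
    multiConditionFlag = c(TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  expect_identical(nrow(altGseaTopTable(summaries, k = 0)), 0L)
  expect_identical(altGseaTopTable(summaries, k = 4)$setName,
                   c("A", "B", "C", "D"))
  expect_message(full <- altGseaTopTable(summaries, k = 10), "returning all")
  expect_identical(nrow(full), 4L)
  top2 <- altGseaTopTable(summaries, k = 2,
                          gseaReport = data.frame(setName = "B",
                                                  direction = "up",
                                                  tier = "significant"))
  expect_identical(top2$gseaTier, c("", "significant"))
})
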
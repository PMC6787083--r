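test_that("both DGE dialects read with correct column mapping and errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tbaseMean\tlog2FoldChange\tstat\tpvalue\tpadj",
               "G1\t10\t0.6\t2.1\t0.03\t0.2"), path)
  tab <- readDgeTable(path, "deseq2", condition = "LF_fed")
  rec <- dgeRecords(tab)
  expect_equal(rec[rec$gene == "G1", c("log2fc", "stat", "p", "padj")],
               data.frame(log2fc = 0.6, stat = 2.1, p = 0.03, padj = 0.2))

  writeLines(c("gene\tlogFC\tt\tP.Value\tadj.P.Val",
               "G1\t0.6\t2.1\tNA\t0.2",
               "G2\t-1.0\t-2.0\t0.01\t0.1"), path)
  vt <- readDgeTable(path, "voom")
  expect_true(is.na(dgeRecords(vt)$p[1]))
  # a missing p excludes the gene from DE selection
  expect_identical(selectDeGenes(vt, "up"), character(0))
  expect_identical(selectDeGenes(vt, "down"), "G2")

  writeLines(c("gene\tlogFC\tt\tP.Value", "G1\t1\t1\t0.5"), path)
  expect_error(readDgeTable(path, "voom"), "adj.P.Val")
  writeLines(c("gene\tlogFC\tt\tP.Value\tadj.P.Val",
               "G1\t1\t1\t0.5\t0.5", "G1\t1\t1\t0.5\t0.5"), path)
  expect_error(readDgeTable(path, "voom"), "duplicate gene")
})

test_that("DGE tables round-trip through the simulator's writers", {
  bundle <- simulateStudy(smallSpec(nConditions = 1, conditionLabels = "c1"))
  for (tab in bundle$tables) {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeDgeTable(tab, path)
    back <- readDgeTable(path, dgeMethod(tab), conditionLabel(tab))
    rec0 <- dgeRecords(tab)
    rec1 <- dgeRecords(back)
    expect_identical(rec1$gene, rec0$gene)
    for (col in c("log2fc", "stat", "p", "padj")) {
      expect_equal(rec1[[col]], rec0[[col]], tolerance = 1e-12, info = col)
    }
  }
})

test_that("ranked lists sort by statistic with deterministic tie-breaking", {
  tab <- dgeTable("c", "deseq2",
                  data.frame(gene = c("A", "B", "C"), log2fc = 0,
                             stat = c(2, -1, 0.5), p = 0.5, padj = 0.5))
  expect_identical(names(makeRankedList(tab)), c("A", "C", "B"))

  tie <- dgeTable("c", "deseq2",
                  data.frame(gene = c("B", "A"), log2fc = 0, stat = c(1, 1),
                             p = 0.5, padj = 0.5))
  expect_identical(names(makeRankedList(tie)), c("A", "B"))

  nas <- dgeTable("c", "deseq2",
                  data.frame(gene = c("A", "B", "C"), log2fc = 0,
                             stat = c(1, NA, 2), p = 0.5, padj = 0.5))
  expect_message(rl <- makeRankedList(nas), "dropping 1")
  expect_identical(names(rl), c("C", "A"))
  expect_error(makeRankedList(dgeTable("c", "deseq2",
    data.frame(gene = "A", log2fc = 0, stat = 1, p = 0.5, padj = 0.5))),
    "fewer than 2")

  # matches an independent sort on simulated data
  tab3 <- simulateStudy(smallSpec(seed = 3, nConditions = 1,
                                  conditionLabels = "c1"))$tables[[1]]
  rec <- dgeRecords(tab3)
  expect_identical(names(makeRankedList(tab3)),
                   rec$gene[order(rec$stat, decreasing = TRUE)])
})

test_that("RNK export round-trips", {
  ranked <- makeRankedList(randomDgeTable(50, seed = 2))
  path <- withr::local_tempfile(fileext = ".rnk")
  writeRnk(ranked, path)
  back <- readRnk(path)
  expect_identical(names(back), names(ranked))
  expect_equal(unname(back), unname(ranked), tolerance = 1e-12)
})

test_that("DE selection applies the dual criteria with strict inequalities", {
  toy <- dgeTable("c", "deseq2", data.frame(
    gene = sprintf("g%d", 1:6),
    log2fc = c(0.6, -0.7, 0.2, 0.5, 0.6, -0.4),
    stat = 1, p = c(0.08, 0.09, 0.04, 0.01, 0.12, 0.06),
    padj = 0.5))
  expect_setequal(selectDeGenes(toy, "up"), c("g1", "g3", "g4"))
  expect_setequal(selectDeGenes(toy, "down"), "g2")

  boundary <- dgeTable("c", "deseq2", data.frame(
    gene = c("exact_lfc", "both_clauses", "zero_lfc"),
    log2fc = c(0.5, -3.0, 0), stat = 1,
    p = c(0.08, 0.001, 0.01), padj = 0.5))
  # |log2fc| not > 0.5 and p not < 0.05: excluded
  expect_false("exact_lfc" %in% c(selectDeGenes(boundary, "up"),
                                  selectDeGenes(boundary, "down")))
  expect_identical(selectDeGenes(boundary, "down"), "both_clauses")
  # log2fc exactly 0 passing on p alone belongs to neither direction
  expect_message(up <- selectDeGenes(boundary, "up"), "log2fc == 0")
  expect_false("zero_lfc" %in% up)
})

test_that("DE selection agrees with the truth-table oracle on random input", {
  withr::with_seed(99, {
    lfc <- c(runif(1000, -2, 2), 0.5, -0.5, 0.6, 0.4, 0)
    p <- c(runif(1000), 0.1, 0.05, 0.1, 0.05, 0.04)
  })
  tab <- dgeTable("c", "deseq2",
                  data.frame(gene = sprintf("g%04d", seq_along(lfc)),
                             log2fc = lfc, stat = 1, p = p, padj = p))
  got <- union(selectDeGenes(tab, "up"), suppressMessages(
    selectDeGenes(tab, "down")))
  want <- tab@records$gene[vapply(seq_along(lfc), function(i) {
    deCriteriaOracle(lfc[i], p[i]) && lfc[i] != 0
  }, logical(1))]
  expect_setequal(got, want)
})

test_that("DE selection is monotone in p and |log2fc|", {
  tab <- randomDgeTable(300, seed = 13)
  up <- selectDeGenes(tab, "up")
  rec <- dgeRecords(tab)
  # decreasing p never removes a gene
  rec2 <- rec; rec2$p <- rec2$p / 2
  expect_true(all(up %in% selectDeGenes(dgeTable("c", "deseq2", rec2), "up")))
  # increasing |log2fc| never removes a gene
  rec3 <- rec; rec3$log2fc <- rec3$log2fc * 2
  expect_true(all(up %in% selectDeGenes(dgeTable("c", "deseq2", rec3), "up")))
})

test_that("method lists combine by mode with conflicts excluded everywhere", {
  perMethod <- list(deseq2 = list(up = c("A", "B"), down = "Z"),
                    voom = list(up = c("B", "C"), down = "Z"))
  expect_setequal(combineMethodLists(perMethod, "union")$up, c("A", "B", "C"))
  expect_identical(combineMethodLists(perMethod, "intersection")$up, "B")
  expect_setequal(combineMethodLists(perMethod, "deseq2_only")$up, c("A", "B"))
  expect_setequal(combineMethodLists(perMethod, "voom_only")$up, c("B", "C"))

  conflicted <- list(deseq2 = list(up = c("A", "B"), down = character(0)),
                     voom = list(up = "B", down = "A"))
  expect_message(res <- combineMethodLists(conflicted, "union"), "conflicting")
  expect_false("A" %in% res$up)
  expect_false("A" %in% res$down)
  expect_identical(res$conflicts, "A")
  # up/down disjoint after combination, provenance recorded
  expect_length(intersect(res$up, res$down), 0)
  expect_identical(res$provenance$methods[res$provenance$gene == "B"],
                   "deseq2;voom")
})
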
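test_that("enrichment score matches the worked examples", {
  # single hit at the top of the list attains ES = 1
  ranked <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  one <- enrichmentScore(ranked, "a")
  expect_equal(one$es, 1)
  expect_identical(one$leadingEdge, "a")

  # scores [4,3,2,1], members at ranks 1 and 3
  r <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  es <- enrichmentScore(r, c("g1", "g3"))
  expect_equal(es$runningSum, c(2/3, 1/6, 1/2, 0), tolerance = 1e-12)
  expect_equal(es$es, 2/3, tolerance = 1e-12)
  expect_identical(es$leadingEdge, "g1")

  # single member at the very bottom: negative ES, leading edge at the tail
  bottom <- enrichmentScore(ranked, "e")
  expect_lt(bottom$es, 0)
  expect_equal(bottom$es, esOracle(unname(ranked), 5), tolerance = 1e-12)
  expect_identical(bottom$leadingEdge, "e")

  expect_error(enrichmentScore(ranked, "zz"), "no gene set member")
  expect_error(enrichmentScore(ranked, names(ranked)), "entire ranked list")
})

test_that("vectorized ES equals the loop oracle for all small sets", {
  # exhaustive: lists of length 3..8 with distinct scores, sets of size <= 3
  withr::with_seed(101, {
    for (N in 3:8) {
      scores <- sort(round(runif(N, -3, 3), 3), decreasing = TRUE)
      while (anyDuplicated(scores)) {
        scores <- sort(round(runif(N, -3, 3), 3), decreasing = TRUE)
      }
      names(scores) <- sprintf("n%02d", seq_len(N))
      for (k in 1:min(3, N - 1)) {
        combos <- utils::combn(N, k)
        for (j in seq_len(ncol(combos))) {
          idx <- combos[, j]
          expected <- esOracle(unname(scores), idx)
          got <- enrichmentScore(scores, names(scores)[idx])$es
          expect_equal(got, expected, tolerance = 1e-12)
          batch <- cofgsea:::.esBatch(matrix(idx, ncol = 1), abs(scores), N)
          expect_equal(batch, expected, tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("batch ES agrees with the scalar path on random permutation sets", {
  withr::with_seed(7, {
    N <- 500
    scores <- sort(rt(N, 10), decreasing = TRUE)
    names(scores) <- sprintf("g%04d", seq_len(N))
    for (k in c(1, 5, 40)) {
      posMat <- vapply(1:50, function(i) sort.int(sample.int(N, k)),
                       integer(k))
      if (k == 1) posMat <- matrix(posMat, nrow = 1)
      batch <- cofgsea:::.esBatch(posMat, abs(scores), N)
      scalar <- apply(posMat, 2, function(idx) {
        enrichmentScore(scores, names(scores)[idx])$es
      })
      expect_equal(batch, unname(scalar), tolerance = 1e-12)
    }
  })
})

test_that("enrichment score agrees with an independent implementation", {
  withr::with_seed(42, {
    N <- 200
    scores <- sort(rnorm(N), decreasing = TRUE)
    names(scores) <- sprintf("g%03d", seq_len(N))
    for (k in c(3, 10, 30)) {
      idx <- sort(sample.int(N, k))
      ours <- enrichmentScore(scores, names(scores)[idx])$es
      ref <- fgsea::calcGseaStat(scores, idx, gseaParam = 1)
      expect_equal(ours, ref, tolerance = 1e-10)
    }
  })
})

test_that("weighted and unweighted statistics differ as expected", {
  r <- c(a = 10, b = 1, c = 0.5, d = 0.1)
  w1 <- enrichmentScore(r, c("a", "c"), weightExponent = 1)$es
  w0 <- enrichmentScore(r, c("a", "c"), weightExponent = 0)$es
  expect_equal(w0, esOracle(unname(r), c(1, 3), w = 0), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(w0, w1)))
  # in the unweighted equal-score case ES of a set mirrors its complement
  eq <- c(a = 1, b = 1, c = 1, d = 1)
  esS <- enrichmentScore(eq, c("a", "b"), weightExponent = 0)$es
  esC <- enrichmentScore(eq, c("c", "d"), weightExponent = 0)$es
  expect_equal(esS, -esC, tolerance = 1e-12)
})

test_that("pre-ranked GSEA is deterministic under the seed and |ES| <= 1", {
  bundle <- simulateStudy(smallSpec(seed = 17, nConditions = 1,
                                    conditionLabels = "c1",
                                    methods = "deseq2"))
  ranked <- makeRankedList(bundle$tables[[1]])
  cfg <- gseaConfig(nPermutations = 100, minSetSize = 1, maxSetSize = Inf,
                    seed = 23)
  r1 <- runPreranked(ranked, bundle$collection, cfg)
  r2 <- runPreranked(ranked, bundle$collection, cfg)
  expect_identical(r1, r2)
  expect_true(all(abs(r1$es) <= 1))
  expect_true(all(r1$fdrQ >= 0 & r1$fdrQ <= 1))
  expect_true(all(r1$pNominal > 0 & r1$pNominal <= 1))
  expect_identical(r1$direction, ifelse(r1$es >= 0, "up", "down"))
  # leading edge is inside the set and the ranked list
  sets <- geneSets(bundle$collection)
  for (i in seq_len(nrow(r1))) {
    le <- r1$leadingEdge[[i]]
    expect_true(all(le %in% sets[[r1$setName[i]]]))
    expect_true(all(le %in% names(ranked)))
  }
})

test_that("a strongly planted set attains the top NES and a small FDR", {
  spec <- simulationSpec(nGenes = 3000, nSets = 50, setSizeRange = c(30, 80),
                         nConditions = 1, conditionLabels = "c1",
                         methods = "deseq2", seed = 31,
                         planted = list(plantedSignal("SET0005", "up",
                                                      responsiveFraction = 1,
                                                      delta = 3)))
  bundle <- simulateStudy(spec)
  ranked <- makeRankedList(bundle$tables[[1]])
  res <- runPreranked(ranked, bundle$collection,
                      gseaConfig(nPermutations = 500, minSetSize = 1,
                                 maxSetSize = Inf, seed = 3))
  expect_identical(res$setName[which.max(res$nes)], "SET0005")
  row <- res[res$setName == "SET0005", ]
  expect_lt(row$fdrQ, 0.05)
  expect_identical(row$direction, "up")
})

test_that("tiered report splits at the configured FDR thresholds", {
  res <- data.frame(setName = c("S1", "S2", "S3"), size = 10L,
                    es = c(0.5, 0.4, -0.3), nes = c(2.5, 1.8, -1.2),
                    pNominal = c(0.001, 0.02, 0.2),
                    fdrQ = c(0.01, 0.2, 0.3),
                    direction = c("up", "up", "down"),
                    leadingEdgeSize = 3L,
                    leadingEdge = I(list("a", "b", "c")),
                    stringsAsFactors = FALSE)
  rep <- reportGsea(res, gseaConfig())
  expect_identical(rep$setName, c("S1", "S2"))
  expect_identical(rep$tier, c("significant", "explorative"))
  expect_identical(nrow(reportGsea(res[0, ], gseaConfig())), 0L)
})

test_that("GSEA results TSV round-trips with leading edges", {
  bundle <- simulateStudy(smallSpec(seed = 8, nConditions = 1,
                                    conditionLabels = "c1",
                                    methods = "deseq2"))
  res <- runPreranked(makeRankedList(bundle$tables[[1]]), bundle$collection,
                      gseaConfig(nPermutations = 50, minSetSize = 1,
                                 maxSetSize = Inf, seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGseaResults(res, path)
  back <- readGseaResults(path)
  expect_identical(back$setName, res$setName)
  expect_equal(back$nes, res$nes, tolerance = 1e-12)
  expect_identical(unname(as.list(back$leadingEdge)),
                   unname(as.list(res$leadingEdge)))
})
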
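smallSpec <- function(...) {
  args <- list(...)
  defaults <- list(nGenes = 1000, nSets = 12, setSizeRange = c(8, 40),
                   cofactorFraction = 0.1, seed = 42)
  do.call(simulationSpec, utils::modifyList(defaults, args))
}

tinyCollection <- function() {
  geneSetCollection(list(S1 = c("A", "B"), S2 = c("B", "C", "D"),
                         S3 = c("E", "F", "G", "H")),
                    c("first", "second", "third"))
}

# random DGE table with n genes, for property tests
randomDgeTable <- function(n = 200, seed = 1, condition = "LF_fed",
                           method = "deseq2") {
  withr::with_seed(seed, {
    t <- rnorm(n)
    p <- runif(n)
    dgeTable(condition, method,
             data.frame(gene = sprintf("g%04d", seq_len(n)),
                        log2fc = rnorm(n, 0, 1), stat = t, p = p,
                        padj = p.adjust(p, "BH"), stringsAsFactors = FALSE))
  })
}
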
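Package: cofgsea
Title: Cofactor-Focused Gene Set Enrichment for Multi-Condition
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pre-ranked gene set enrichment analysis (weighted running-sum
    enrichment score, gene-set permutation null, NES and permutation FDR,
    leading-edge extraction) together with two risk-ratio statistics for
    coenzyme-A and NAD(P)(H) cofactor biology: overrepresentation of
    cofactor genes among a set's contributing (leading-edge) genes, and an
    alternative, direction-aware enrichment that ranks gene sets by their
    share of differentially expressed genes per condition, aggregates ranks
    across conditions by the median, and flags sets overrepresented in two
    or more conditions. Includes a seeded synthetic generator of
    multi-condition, dual-dialect (DESeq2- and limma-voom-style)
    differential-expression tables with planted pathway signals, plus
    readers and writers for GMT, RNK and TSV interchange formats and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AAA-generics.R'
    'AllClasses.R'
    'altGsea.R'
    'cofactorRR.R'
    'cofgsea-package.R'
    'dge.R'
    'genesets.R'
    'gsea.R'
    'specs.R'
    'pipeline.R'
    'simulate.R'
    'utils.R'
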
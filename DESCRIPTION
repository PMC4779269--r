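Package: lowpdeg
Title: Comparative Expression Profiling Under Low-Phosphate Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative microarray expression
    profiling of phosphate-starvation experiments with a 2x2x2 factorial
    design (two accessions, two tissues, two phosphate treatments, three
    biological replicates). Implements quantile normalization and
    median-polish summarization, SAM-style permutation differential
    expression with a three-part DEG criterion (two-fold change,
    FDR-adjusted significance, complete triplicates), cross-accession and
    cross-tissue pattern classification with a four-fold rescue rule
    ("marked DEGs"), multi-way set intersection with non-redundancy
    accounting, hypergeometric gene-set enrichment, and two-way
    hierarchical clustering. Ships a synthetic-data generator emulating
    the full design with planted differential expression and pattern
    structure so every stage is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    limma,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
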
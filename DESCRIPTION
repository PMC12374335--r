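Package: methinherit
Title: Window-Based DMR Calling and Cross-Generation Methylome Integration
    for Whole-Genome Bisulphite Sequencing
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing per-cytosine bisulphite methylation counts:
    parsing cytosine-report files, context classification (CpG/CHG/CHH),
    global methylation summaries and bisulphite conversion-rate estimation,
    window-based differential methylation calling with a pooled two-group
    Fisher exact test and fold-change rule, promoter/gene-body annotation of
    differentially methylated regions to genes, and cross-generation /
    cross-omics integration producing shared-gene sets and
    direction-concordance tables. A bundled synthetic bisulphite-methylome
    generator (beta-binomial counts, planted differential regions,
    configurable cross-generation inheritance and coupled expression tables)
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
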
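Package: fracscore
Title: Compartment Enrichment Scoring for Fractionated Embryo RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies transcripts from time-resolved, biochemically
    fractionated Drosophila embryo RNA-seq into spatiotemporal contexts
    (early syncytial, late blastoderm, nuclear, cytoplasmic) using
    per-gene enrichment ratios and an adaptive cutoff on the log-range of
    each score distribution. Includes median-of-ratios count
    normalization, fold-change screening of transcripts depleted in
    checkpoint and histone mRNA processing mutants, gene-set overlap
    statistics, a negative-binomial simulator with planted ground truth
    for end-to-end validation, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
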
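Package: plantfit
Title: Fitness Analysis of Barcoded Transposon Mutant Libraries Colonizing Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for randomly barcoded transposon sequencing (TnBarSeq)
    screens of bacterial colonization across plant hosts and organs: barcode
    extraction and counting, per-strain and per-gene fitness scores against a
    soil reference, mixed-effects differential-fitness tests with a
    residual-normality gate and false-discovery-rate control, cross-habitat
    specificity classification and COG-category enrichment. Also provides the
    companion analyses of an efflux-pump screen follow-up: protein-family
    clade calling by alignment-score dissimilarity, neighbor joining and
    most-recent-common-ancestor extraction; a recombinant-inbred-line allele
    fraction linkage scan; a combinatorial glucosinolate breakdown-product
    rule engine; and dose-response (Hill/IC50), qPCR delta-delta-Ct and
    growth-curve endpoint computations. A synthetic-data generator emulates
    the statistical structure of such screens so every stage is testable
    without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    Biostrings,
    ape,
    phangorn,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
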
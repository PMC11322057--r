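Package: triadtest
Title: Family-Triad Genetic Association Testing for Maternal-Fetal Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Case-control and family-based association analysis for
    mother-father-offspring triad studies of biallelic SNPs, as used in
    maternal-fetal immunogenetics (e.g. maternal KIR2DL4 x fetal HLA-G in
    preeclampsia). Implements allelic and genotypic case-control tests with
    crude odds ratios and Woolf confidence intervals, dominant/recessive
    genotype collapsing, Hardy-Weinberg goodness-of-fit testing, Mendelian
    consistency checking, the transmission disequilibrium test (TDT) with
    parent-of-origin stratification, maternal-by-fetal combined-genotype
    association, a seeded synthetic triad-cohort generator for calibration
    and power studies, and a consistency audit that recomputes published
    statistics from their count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
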
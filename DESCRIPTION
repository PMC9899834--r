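Package: thelytools
Title: Inference of Thelytoky Cytological Mechanisms from Genetic Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diagnosing the cytological mechanism of thelytokous
    parthenogenesis (apomixis versus automixis with central fusion, terminal
    fusion, gamete duplication, or random fusion) from parent-offspring
    microsatellite genotypes. Provides a chromatid-level simulator of meiosis
    and diploidy restoration, closed-form and enumerated expected rates of
    transition to homozygosity, Fisher exact tests of observed against
    expected rates, per-locus marker statistics (allele counts, observed and
    expected heterozygosity, polymorphic information content), a
    microsatellite (SSR) scanner with perfect/compound/imperfect
    classification, and karyotype classification from chromosome arm
    measurements. Seeded synthetic-data generators make every pipeline stage
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
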
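Package: noiapoe
Title: Orthogonal One-Locus Association Models with Parent-of-Origin Effects
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: One-locus genetic association analysis that models parent-of-origin
    effects (POE) over ordered maternal/paternal genotypes within the natural
    and orthogonal interactions (NOIA) framework. Provides functional and
    statistical (frequency-orthogonal) design codings with and without a POE
    term, exact transformations between parameterizations, the orthogonal
    decomposition of genetic variance into two additive components and a
    dominance component, linear and logistic Wald-test inference, seedable
    quantitative-trait and case-control simulators based on genotype
    penetrances, and a Monte-Carlo engine for power and type-I-error studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
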
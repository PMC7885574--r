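Package: connekt
Title: Genetic Connectedness Analysis from Pedigree and Genomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures genetic connectedness between management units
    (herds, flocks, contemporary groups) in livestock genetic evaluation.
    Builds numerator (pedigree) or genomic relationship matrices, assembles
    Henderson's mixed model equations, and computes prediction error
    variance (PEV) based statistics (PEVD, CD, r) with individual-average,
    group-average and contrast summaries, as well as statistics based on
    the variance of unit-effect estimates (VED, CDVED, CR) with exact
    fixed-effect corrections. Includes a gene-dropping simulator that
    generates multi-generation pedigrees, linked marker genotypes,
    relationship-based unit assignments and phenotypes for method
    evaluation, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
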
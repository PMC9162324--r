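Package: balsel
Title: Detecting Balancing Selection from Shared and Private Polymorphisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A test for balancing selection that contrasts the ratio of
    nonsynonymous to synonymous polymorphisms among variants shared between
    two populations with the same ratio among variants private to one of
    them (the Z statistic), together with estimators of the proportion
    (alpha_b) and number (b) of shared nonsynonymous polymorphisms directly
    maintained by balancing selection. Includes significance machinery
    (chi-squared and one-tailed Fisher tests, gene-level bootstrap
    confidence intervals), classification of two-population SNP data into
    shared/private categories and folded minor-allele-frequency bins with
    GC-biased gene conversion, recombination-rate and gene-set filters, and
    a forward Wright-Fisher simulation framework (gamma distributions of
    fitness effects, selection-dependent dominance, negative
    frequency-dependent balanced polymorphisms, population splits with
    vicariance, dispersal, expansion and migration) used to validate the
    test under demographic change.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
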
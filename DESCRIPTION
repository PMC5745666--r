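Package: gsacc
Title: Expected Precision of Genomic Estimated Breeding Values
Version: 0.1.0
Authors@R:
    person("gsacc", "developers", email = "gsacc@example.org", role = c("aut", "cre"))
Description: Deterministic prediction of the expected precision (squared
    accuracy, reliability) of genomic estimated breeding values (GEBV) from
    breeding-scheme design parameters: reference population size, number of
    SNPs, heritability and the allele-frequency distribution of the marker
    panel. Implements the exact Monte-Carlo expression based on the expected
    inverse of the ridge coefficient matrix, its first- and second-order
    Taylor closed forms under uniform and U-shaped allele-frequency laws,
    earlier published comparators (Daetwyler; Goddard), a single-prior-variance
    (GBLUP-style) first-order formula, and the multivariate generalisation for
    selection-index reliability. A built-in simulator (Hardy-Weinberg
    genotypes in linkage equilibrium, SNP-BLUP evaluation) validates every
    approximation, and a command-line interface reproduces the reference
    result grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
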
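Package: rcpmeth
Title: Ratio of Concordance Preference for Double-Stranded DNA
    Methylation Patterns
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the balance of conservative, random, and dispersive
    DNA-methylation processes from double-stranded (hairpin-bisulfite)
    methylation patterns using the Ratio of Concordance Preference (RCP),
    the ratio 2*sqrt(MU)/H of observed concordance to the random
    expectation at CpG/CpG dyads. Provides parsing, validation, and
    barcode-based deduplication of per-molecule pattern files; the (m, U)
    configuration-space geometry with conservative, random, and dispersive
    boundaries and RCP contours; mathematical correction for failed and
    inappropriate bisulfite conversion; read-level BCa bootstrap and
    multinomial profile-likelihood confidence intervals; maximum-likelihood
    comparison, permutation, and replicate-heterogeneity tests with
    heterogeneity-gated pooling; a simulator for double-stranded patterns
    with known methylation frequency, RCP, within-read correlation, and
    injected conversion errors; and plotting of data sets in (m, U) space.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
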
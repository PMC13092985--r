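Package: stemwobble
Title: Anticodon-Stem Architecture of Bacterial tRNAs and Extended
    Superwobble Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for surveying bacterial tRNA genes with shortened
    (4-base-pair) anticodon stems. Parses tRNAscan-SE secondary-structure
    output, annotates cloverleaf arms, bins anticodon-stem length with a
    bulge-tolerant rule, and flags Blastocrithidia-like tRNA-Trp(CCA)
    variants (4-bp stem, 7-nt loop, no A9C/G24A substitutions). Provides
    genome-level inventories (species abundance, stop-codon usage,
    correlation analyses), the statistical procedures used to evaluate the
    extended superwobble hypothesis (proportion Z-test, normality-gated
    two-group comparison, Welch t, one-way ANOVA, Cohen's d), a
    stop-to-tryptophan UGA reassignment validation workflow (conceptual
    translation under alternative genetic codes, C-terminal extension
    screening, suppressor-tRNA check), a codon-decoding rule engine
    covering Crick wobble, superwobble and the extended superwobble C:A
    rule, and seeded synthetic-data generators with planted ground truth
    for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
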
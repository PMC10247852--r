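Package: ffpewes
Title: Validation and Triage Toolkit for FFPE Whole-Exome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating whole-exome sequencing of formalin-fixed
    paraffin-embedded (FFPE) material in a molecular-autopsy setting.
    Implements ensemble multi-caller consensus call sets, stratified variant
    concordance (sensitivity and positive predictive value against a truth
    catalogue or a matched blood sample), discovery of problematic regions by
    sliding-window clustering of discordant calls, targeted-capture coverage
    quality control (fold-80 base penalty, sequencing-success rule, joint
    low-coverage detection, gene-level coverage curves), pre-library QC
    advisories, and tiered gene-panel variant triage with diagnostic-yield
    accounting. A seeded simulator generates matched truth/blood/FFPE call
    sets and coverage tracks with planted error structure so the whole
    pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    vcfR,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
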
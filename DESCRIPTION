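Package: polqscars
Title: DSB Repair Scar Classification and Mutational Signature Cohort
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterising DNA double-strand break (DSB) repair
    outcomes from deep amplicon sequencing and for testing mutational
    signature enrichment in stratified tumour cohorts. The junction arm
    aligns amplicon reads, extracts deletion and insertion events,
    measures junction microhomology, flags polymerase theta-mediated end
    joining (TMEJ) scars, classifies templated insertions by origin
    (distant, nearby, snapback, direct repeat, random) and filters
    sequencing background with Poisson read-count cutoffs. The cohort arm
    classifies variants into the 96 single-base-substitution and 83
    small-indel channels, stratifies samples by gene mutation status and
    expression tertile, and tests signature exposures between strata with
    rank-based tests and Bonferroni correction. Both arms ship
    ground-truth simulators so every analysis step is testable against
    planted outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
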
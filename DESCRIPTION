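Package: linetester
Title: Line x Tester Combining Ability, Heterosis and Marker Diversity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complete analysis chain for balanced line x tester mating designs in
    plant breeding: randomized-complete-block analysis of variance with the
    standard parent/cross partition, general and specific combining ability
    (GCA/SCA) with standard errors and critical differences, genetic variance
    components with narrow-sense heritability, genetic advance and
    predictability ratio, mid-parent and better-parent heterosis with
    significance tests, codominant microsatellite diversity statistics (allele
    counts, observed and expected heterozygosity, polymorphism information
    content), simple-matching and Euclidean distance matrices with UPGMA and
    neighbour-joining trees, the Evanno delta-K summary of population-structure
    log-likelihoods, and correlation analyses linking genetic distance and
    combining ability to heterosis. Includes generators for synthetic balanced
    trials and structured marker panels with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
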
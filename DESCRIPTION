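Package: oenotype
Title: Phenotype-Based Preselection of Indigenous Wine Yeast Starters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening pipeline for preselecting indigenous wine yeast
    fermentation starters from large isolate collections. Encodes five
    phenotypic plate assays (killer toxin reaction, hydrogen sulphide
    production, acetic acid production, sulphur dioxide resistance and
    beta-glucosidase activity) into ordinal five-digit phenotype codes,
    clusters the codes by Ward's method with a largest-gap rule for
    choosing the number of groups, groups PCR fingerprint band patterns
    by Dice similarity and UPGMA, analyses free-sorting sensory data via
    co-occurrence matrices, runs a one-way ANOVA battery with assumption
    diagnostics for hydrogen sulphide production, and validates the
    phenotypic grouping against fermentation outcome and sensory group.
    Includes seeded synthetic-data generators emulating the statistical
    structure of such screening studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
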
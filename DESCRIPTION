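Package: duogrs
Title: Transmitted and Non-Transmitted Allele Genetic Risk Scores from
    Mother-Child Duos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers parent-of-origin allelic transmission in mother-child
    duos from phased genotypes, builds haplotype-resolved weighted genetic
    risk scores (maternal transmitted, maternal non-transmitted and
    paternal transmitted), and fits the linear, case-cohort and
    exposure-based-cohort models used to separate direct genetic
    transmission from maternal genetic-nurture effects on childhood
    overweight. Includes a trio cohort simulator with Mendelian
    transmission in haplotype blocks, polygenic phenotypes, phenotypic
    assortative mating, phasing switch errors and the three BMI-based
    sampling groups, so the whole pipeline is testable end to end without
    access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
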
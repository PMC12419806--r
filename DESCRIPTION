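Package: allelome
Title: Allele-Specific Expression Atlases from Reciprocal F1-Hybrid RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping the allelome - the genome-wide landscape of
    allelic expression states - from reciprocal F1-hybrid RNA-seq designs.
    Builds strain-specific ("diploid") transcript references from a variant
    table, assigns reads to alleles at diagnostic positions, tests allelic
    imbalance with a tolerance-filtered sign-flip resampling test in parental
    or strain orientation, classifies every gene by condition as maternal,
    paternal, strain-biased or biallelic using reciprocal-cross concordance,
    assembles condition-resolved atlases, and applies candidate-gene screens
    over differential-expression tables. Includes a synthetic-data generator
    with planted ground truth (negative-binomial totals, beta-binomial
    allelic fractions, optional alignment bias) for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
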
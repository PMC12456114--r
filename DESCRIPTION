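Package: labreed
Title: Local-Ancestry-Aware Selection for Hybridized Captive Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time simulation of a hybridized captive-breeding
    population with haplotype-resolved tracking of genotype, local ancestry
    and founder origin, together with a family of local-ancestry-aware
    selection measures (kinship, heterozygosity, admixture and their
    ancestry-masked and weighted variants) and ranked mean-kinship style
    breeding algorithms that remove introgressed ancestry while preserving
    diversity of the conservation target population. Includes a
    Balding-Nichols founder model, an introgression-pulse wild history,
    bottleneck-and-selection captive formation, demographic calculations for
    expected lifetime offspring, sensitivity sweeps, and readers and writers
    for phased haplotype/ancestry matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
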
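Package: rwmapkit
Title: Genetic Mapping and Positional Cloning Toolkit for Balancer-Region
    Lethal Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infrastructure for localizing recessive lethal mutations
    recovered in a balancer-chromosome mutagenesis screen, modeled on the
    mapping of ENU-induced lethals in the rump-white (Rw) region of proximal
    mouse chromosome 5. Provides exact genomic interval algebra; critical-
    region inference by interval exclusion from deletion-complementation
    tests and F2 intercross recombination data; overlap-driven
    complementation-test planning, transitive allelic grouping, and
    balancer-intercross viability chi-square statistics; candidate-variant
    filtering (heterozygous, unique to the mutant sample, inside the
    critical region, absent from known-variant catalogs); and a synthetic
    balancer-screen simulator with known ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
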
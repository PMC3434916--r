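Package: sundapop
Title: Multilocus Nuclear Sequence Population Genetics for Two-Group
    Phylogeography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multilocus phased nuclear haplotype data
    from structured tree populations: per-locus diversity summaries (pi by
    site category, haplotype diversity, Watterson's theta), Tajima's D with
    fixed-S coalescent nulls, McDonald-Kreitman and multilocus HKA
    neutrality tests, Hudson Fst / net divergence (Da) with neighbor-joining
    trees, STRUCTURE-style admixture clustering with Evanno delta-K model
    selection, composite-likelihood recombination-rate estimation, and
    isolation-with-migration demographic inference by synthetic likelihood
    with nested-model likelihood-ratio tests and conversion of coalescent
    parameters to effective sizes, divergence times and migration rates.
    Includes coalescent simulators (standard neutral, ancestral
    recombination graph, two-deme isolation-with-migration) and a synthetic
    data generator emulating a seven-population, five-locus sampling design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
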
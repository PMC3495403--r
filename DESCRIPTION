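Package: karyomapr
Title: Sex-Specific Linkage Maps and Comparative Karyotype Analysis
Version: 0.1.0
Authors@R:
    person("karyomapr", "developers", email = "karyomapr@example.org",
           role = c("aut", "cre"))
Description: Construction of sex-specific genetic linkage maps from pedigree
    SNP genotypes (two-point recombination fractions by EM over unknown
    parental phase, LOD-score grouping, seriation ordering with
    reference-based tie-breaking, Haldane/Kosambi map functions), alignment
    of maps from two populations on shared markers, and classification of
    chromosomal rearrangements (Robertsonian and tandem fusions, fissions,
    whole-arm translocations) together with the karyotype arithmetic they
    imply (2n, NF, metacentric/acrocentric counts).  A synthetic-data module
    simulates karyotypes, rearranged genomes, pedigrees and meioses with
    sex-specific crossover distributions so every stage of the pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
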
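Package: rsgenepool
Title: Simulation and Genomic Analysis of Interspecific Recurrent-Selection Gene Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying gene pools of the allopolyploid oilseed crop
    Brassica napus reconstituted by introgression from its related species
    B. rapa (A genome) and B. carinata (B and C genomes). Provides a forward
    simulator of a mass recurrent-selection breeding scheme mediated by
    dominant genic male sterility, with mosaic subgenome ancestry tracking and
    SSR/SNP-style marker ascertainment; classification of marker loci and
    alleles by subgenome origin from presence patterns across reference taxa;
    population diversity statistics (alleles per locus, gene diversity,
    observed heterozygosity, Nei genetic distance) and neighbor-joining
    clustering; multi-reference introgression calling against a recurrent
    parent with missing-rate filtering and marker-supported segment merging;
    and recurrent-selection genetic-gain statistics with per-generation trait
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
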
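Package: numtkit
Title: Detection and Population-Genetic Analysis of Polymorphic Nuclear
    Mitochondrial DNA Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for calling polymorphic nuclear insertions of
    mitochondrial DNA (NUMTs) from abstracted discordant-pair and
    split-read evidence, merging calls across a cohort, testing their
    co-occurrence with archaic introgressed segments by permutation,
    scanning them for population-specific selection with the population
    branch statistic (PBS) and a block jackknife, locating insertion and
    origin hotspots by permutation enrichment on the nuclear and circular
    mitochondrial genomes, building per-individual and representative
    consensus sequences from pileups, testing for recurrent insertion via
    pairwise identity with hypervariable-region masking, and classifying
    mitochondrial reading-frame integrity under the vertebrate
    mitochondrial genetic code.  A seeded synthetic-data module generates
    every input the pipeline consumes, with planted ground truth for
    recovery and calibration tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
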
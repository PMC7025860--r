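Package: censcape
Title: Centromere Landscapes and Karyotype Evolution in Compact Fungal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts short regional centromeres in compact fungal genomes
    from their chromosomal GC landscape, scores AT-rich sequence motifs with a
    position weight matrix and a column-shuffled control, calls
    kinetochore-bound regions from ChIP coverage by input subtraction,
    implements qPCR percent-of-input and histone depletion arithmetic,
    classifies centromere fates (breakage versus inactivation) from gene
    synteny between genomes, and infers ancestral chromosome numbers by Fitch
    parsimony. Includes a seeded synthetic-genome generator with planted
    centromere cores, motif sites, gene annotations, simulated ChIP coverage
    and karyotype rearrangement operators, so every stage of the analysis can
    be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    methods,
    ape,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
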
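Package: micropopgen
Title: Within-Species Population Genetics from Metagenomic Read Mappings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Strain-level population genetics for abundant but uncultivated
    microbial species tracked across environmental metagenomes. Starting from
    per-sample read alignments against a representative genome, the package
    applies read-pair quality filters, builds base-count pileups, computes
    per-site and per-gene nucleotide diversity at nested pooling scales
    (sample, replicate, plot, block, meadow), calls SNPs against a
    sequencing-error null model with an allele-frequency cutoff, measures
    linkage disequilibrium (r-squared and D-prime) between variant pairs
    co-observed on read pairs, computes per-gene Hudson F_ST between
    geographic blocks as a ratio of averages, and scans for gene-specific
    selective sweeps with a moving-window test confirmed by linkage and
    diversity statistics. A coalescent-free synthetic-data generator emits
    aligned paired reads with truth tables so every stage can be validated
    against known population parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    yaml,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
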
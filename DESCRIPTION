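Package: tdnascout
Title: Forensic Detection of T-DNA Inserts, Splinters and Associated
    Variation in Resequenced Transgenic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates T-DNA and vector-backbone inserts in short-read
    resequencing data of transgenic plants by classifying broken read
    pairs and split reads against a hybrid host-plus-plasmid reference,
    reconstructs integration junctions (site microdeletions, filler DNA,
    and small border-free "splinter" fragments), calls transformant-unique
    heterozygous small variants with a stringent/lenient two-tier filter,
    and detects insert-associated structural variation (large heterozygous
    deletions from coverage drops, insert-flanking translocations from
    cross-chromosome evidence). Includes a deterministic simulator of
    diploid transgenic genomes and paired-end reads with full ground
    truth, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
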
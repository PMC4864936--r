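Package: scafex
Title: Exact Repeat-Aware Genome Scaffolding from Mate-Pair Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs a scaffold graph from paired-read mappings across
    multiple jumping libraries, finds minimal-repeat optimal scaffolds that
    globally minimize the number of discordant scaffold edges via a memoized
    fixed-parameter exact search over fenced subgraphs, and estimates gap
    sizes by maximum likelihood. Includes truncation-bias-corrected edge
    length estimation, coverage-based repeat classification, conversion of
    long-read contig links into synthetic mate-pair libraries, a synthetic
    data generator (genomes with planted repeat families, contigs, mate
    pairs), a brute-force scaffolding oracle, and a truth-based evaluator
    (corrected N50, inversion/translocation/relocation/indel error classes,
    repeat placement metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
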
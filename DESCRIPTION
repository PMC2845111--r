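Package: irbkit
Title: Identical Repeated Backbone Detection and Copy-Number Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive detection of 100%-identical repeats above a length
    threshold in a genome assembly, in direct or inverted orientation, within
    and between chromosomes. Maximal repeat pairs are decomposed into a
    non-redundant set of Identical Core sequences (ICs), which are merged into
    non-overlapping Identical Sequence Tracks (ISTs); the set of ISTs forms
    the Identical Repeated Backbone (IRB) of the assembly, a map of minimal
    substrates for non-allelic homologous recombination. The package also
    provides bp-level overlap analysis of the IRB against annotation interval
    sets (segmental duplications, copy-number variant catalogues), inference
    and consistency classification of sets of identical gene copies, an
    in-silico hybridization screen that flags gene copy-number changes in raw
    sequencing reads against a resampled single-copy null, seeded simulators
    for genomes with planted duplications and read sets with planted
    copy-number changes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
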
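Package: fourTran
Title: Chromosome-Conformation Profiling from Transposable-Element Viewpoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for 4C-style chromosome-conformation analysis anchored at
    repetitive transposable-element (TE) viewpoints. Covers restriction-map
    construction and the reduced genome of unique cut-site flanks, primer-pair
    design on TE family consensus sequences, genome-wide in-silico PCR
    prediction of bait sites, statistical detection of observed bait profiles
    and strain-specific insertions from fragment-level 4C counts,
    capture-based anchor detection from read pairs with probe-target
    prediction and size-factor normalized signal tracks, A/B compartment and
    TAD context classification of interactions, permutation-based feature
    enrichment with a chromosome-preserving shuffle, and a seeded simulator of
    genomes with planted TE insertions, bait-centric 4C reads and capture
    read pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
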
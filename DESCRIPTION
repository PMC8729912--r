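Package: prgscan
Title: Profile-HMM Annotation of Plant Pathogen-Recognition Genes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Annotates plant pathogen-recognition genes (PRGs) from protein or
    nucleotide sequence. Builds per-domain profile hidden Markov models from
    reference multiple sequence alignments, filters them by the retention
    criteria used for curated resistance-gene databases, and calibrates a
    minimum BLOSUM62 hit-score threshold per model. Proteomes are scanned with
    log-odds local Viterbi alignment for the resistance domains TIR, NBS, LRR,
    LysM, lectin and kinase; coiled-coil and transmembrane segments are
    predicted with heptad-propensity and hydropathy sliding-window models.
    Detected domain architectures are classified into the seven canonical PRG
    classes (CNL, TNL, RLK, RLP, LYK, LYP, LECRK) or non-canonical architecture
    codes, and predictions are benchmarked against reference annotations with
    criterion-based agreement counts and confusion-matrix metrics. A
    synthetic-data generator plants known architectures with exact truth
    tables so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
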
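Package: rufscan
Title: Comparative RNA-Seq Discovery of Candidate Noncoding RNAs in
    Bacteria and Archaea
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for identifying candidate noncoding
    RNAs (RNAs of Unknown Function, RUFs) from bacterial and archaeal
    RNA-seq coverage tracks. Calls expressed, unannotated regions of
    bounded length from per-base read-depth tracks; ranks features by
    median read depth within each strain and aggregates expression across
    strains by minimum rank; estimates pairwise strain distances from SSU
    rRNA alignments under the F84 substitution model; scores gene-family
    conservation by maximum pairwise distance; derives conserved-fraction
    curves and classifies strain pairs relative to the 'Goldilocks Zone'
    of phylogenetic distances where comparative RNA analysis is
    informative; integrates conservation, structure and cross-strain
    expression evidence; and computes RNA-seq dataset quality-control
    metrics including a positional concordance statistic. Includes a
    synthetic-data generator (strain phylogenies, SSU sequences evolved
    under F84, distance-dependent family loss, coverage tracks with
    planted RUFs) providing ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
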
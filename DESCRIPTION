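Package: editscan
Title: Genome-Wide Identification and Annotation of RNA-Editing Sites
    from Matched DNA-Seq and RNA-Seq Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and annotates RNA-editing sites genome-wide from
    matched, pre-aligned DNA-seq and RNA-seq data. Implements
    ploidy-aware homozygous genotype calling (Bayesian, binomial and
    allele-frequency models applicable to single individuals or pooled
    samples of known ploidy), a splice-junction library builder with
    coordinate lift-over for junction-mapped reads, a cascade of
    false-positive filters (non-redundant read support, editing level,
    base quality, known-SNP exclusion, multi-type exclusion, mid-read
    support, splice-distance, homopolymer, DNA depth cap and an internal
    seed-and-extend realignment check), an exact binomial test against
    sequencing error with Benjamini-Hochberg FDR control, cross-sample
    retrieval of low-level sites, and annotation of editing sites with
    genomic features including codon and amino-acid changes. A
    self-contained simulator generates genomes, gene models, planted
    variants and editing sites, and truth-aligned reads for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
biocViews: Transcriptomics, RNASeq, Sequencing, SNP, Alignment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
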
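Package: pollenxloc
Title: Characterization of Pollen-Expressed Intergenic Loci from Assembled Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end characterization of novel intergenic expressed loci
    (XLOCs) discovered in pollen RNA-seq experiments. Groups assembled
    transcript models into loci, classifies them against reference
    annotations (novel versus recently annotated), assigns biotypes (short
    RNA, lncRNA, lincRNA, ORF-coding) from spliced length, open reading
    frames, gene distance and transposable-element overlap, computes
    expression-threshold calls (pollen-expressed, highly expressed,
    pollen-specific) and negative-binomial Wald differential expression
    across datasets, assigns phylostrata from homology-hit lineages, scores
    plant miRNA target sites with an expectation penalty, and calls
    translation likelihood from ribosome P-site frame periodicity. Includes
    a synthetic-data generator with full ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
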
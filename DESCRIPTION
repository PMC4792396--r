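Package: mitocn
Title: Mitochondrial DNA Copy Number Estimation and Association Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates mitochondrial DNA copy number (mtCN) per diploid cell
    from whole-genome sequencing coverage and from droplet digital PCR (ddPCR)
    droplet counts, with the quality-control rules used in multi-tissue
    population studies: poly-N masking of the reference to obtain mappable
    bases, insert-size based fragment tallying from paired-end alignments,
    Grubbs-test exclusion of noisy samples and high-variance chromosomes, and
    a probability model for false alignment of reads deriving from nuclear
    insertions of mitochondrial DNA (NUMTs). Includes the downstream
    statistical battery relating mtCN to age, sex, haplogroup, heteroplasmy
    burden and site-specific minor allele frequencies (linear and partial
    regression, Pearson correlation, Benjamini-Hochberg correction), and a
    synthetic-data generator that produces reference genomes, alignments,
    ddPCR measurements and multi-tissue cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
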
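Package: dibench
Title: Benchmarking Assemblies, Reads, and Variant Call Sets Against a
    Diploid Truth Genome
Version: 0.1.0
Authors@R:
    person("Q.", "Benchwright", email = "qbench@example.org",
           role = c("aut", "cre"))
Description: Evaluates test genome assemblies, aligned sequencing reads, and
    phased variant call sets against a complete diploid truth genome.
    Implements haplotype-specific k-mer markers with a two-state hidden
    Markov model for phase-block segmentation and switch-rate estimation,
    NGAx contiguity curves from alignments broken at large indels,
    phase-aware discrepancy cataloging with alignment-based Phred-scaled
    quality values, mononucleotide-run accuracy, read error spectra and
    base-quality calibration, coverage dispersion and GC bias profiling,
    and construction of variant-derived genomes with genotype-quality
    masking.  A fixtures module simulates diploid genomes, corrupted
    assemblies, and reads with fully known truth so the whole suite is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
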
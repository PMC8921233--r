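Package: repcall
Title: Somatic SNV Calling in Repetitive Genomic Regions by Copy Collapse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls somatic single-nucleotide variants in repetitive regions of
    tumour genomes where conventional callers fail because mutant reads are
    diluted across near-identical copies. Regions of interest are screened for
    self-homology to define repetitive regions of interest (RROIs), all reads
    mapped to any copy of an RROI are realigned onto a single flanked
    reference copy, and tumour-versus-matched-normal candidates are called
    from the collapsed pileups. Candidates are filtered by a mutant-read
    genome re-check, in-cis haplotype concordance, base-quality, strand- and
    position-bias criteria, a beta-binomial Monte-Carlo posterior on the
    tumour versus control mutant allele frequency, and an optional panel of
    normals. A synthetic-genome spike-in benchmark generates repeat families,
    paired tumour/normal reads and ground-truth mutations so the whole
    pipeline can be exercised and scored (sensitivity, precision) without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
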
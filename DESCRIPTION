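Package: intequant
Title: Molecular Characterization of Nuclease-Free AAV Targeted Gene Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and characterizes AAV-mediated, nuclease-free targeted
    gene integration from sequencing and droplet-digital PCR data. Implements
    junction k-mer counting of 3-primer amplicon reads with standard-curve
    correction, Poisson linkage analysis of four-class ddPCR droplet counts,
    low-frequency pileup variant calling with de novo mutation criteria and
    limit-of-detection panels, localization of homologous-recombination
    crossovers from inherited heterozygous SNP allele frequencies, and
    classification of long reads for residual viral ITR sequence at
    integration junctions. Ships seeded simulators that generate every input
    class (short paired-end amplicon reads, control panels, Nanopore-like long
    reads, droplet tables) so all pipelines can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    withr,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    BiocGenerics
Config/testthat/edition: 3
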
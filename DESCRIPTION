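Package: chalcidEvo
Title: Comparative Molecular Evolution Toolkit for Chalcid Wasp Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analyses of protein evolutionary rates and genome features
    across parasitoid wasp (Chalcidoidea) genomes: root-to-clade
    branch-length place ranking of single-copy orthologs with
    rank-discrepancy scoring and binned fast/slow gene selection,
    Tajima's relative rate test on triple alignments with a
    divergence-masking filter and concatenated whole-set testing,
    chi-squared goodness-of-fit and pairwise post-hoc machinery with
    hypergeometric term enrichment, OrthoMCL-style gene-family category
    and missing-family accounting, GFF3 gene-model handling with
    exon/intron length comparisons and spliced CDS extraction, gene-body
    CpG observed/expected and bisulfite fractional-methylation
    classification with cross-species conservation accounting, and
    Nei-Gojobori dN/dS coding divergence with variant-effect
    classification. A synthetic-data generator with recorded ground
    truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
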
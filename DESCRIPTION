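Package: DuplexSelect
Title: Somatic Mutation, Selection and Phasing Analysis for Ultra-Deep
    Duplex Sequencing Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing error-corrected duplex sequencing of
    targeted gene panels in normal tissues: a post-pipeline variant filter
    cascade (depth, no-call fraction, germline VAF, region mask, recurrent
    artifacts, cross-sample germline exclusion), mutation frequency and
    burden statistics with covariate regressions, pseudocounted dN/dS
    selection inference with bootstrap uncertainty, rule-based
    pathogenicity annotation from a user-supplied score table, read-backed
    phasing of somatic variants against a germline heterozygous site with
    exact binomial tests for phase bias and protein-domain enrichment, and
    codon-level hotspot recurrence. A synthetic-cohort generator emulates
    the statistical structure of a duplex-sequenced cohort (depth tracks,
    clone sizes, gene-specific selection, germline SNPs, recurrent
    artifacts, phased reads) so that every stage is testable end to end
    without external data.
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
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, SomaticMutation, VariantAnnotation, Software
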
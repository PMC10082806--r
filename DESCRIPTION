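Package: nanodmr
Title: Differential Methylation Calling for Nanopore Methylomes with a
    Heterogeneous Shifting-Level Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls differentially methylated regions (DMRs) between two
    long-read methylomes from per-CpG-group methylation frequencies.
    Delta-beta profiles are segmented with a heterogeneous shifting-level
    model whose jump probability depends on the distance between
    consecutive CpG groups and whose emissions are truncated Gaussians on
    [-1, 1]; segments are tested with the Wilcoxon rank-sum test and
    classified as hyper- or hypo-methylated.  Downstream utilities
    annotate DMRs to CpG-island context and genic elements, measure
    observed-versus-expected enrichment in genomic features with a Monte
    Carlo null, and compute read-level methylation entropy.  A synthetic
    methylome generator and benchmark scorer support in-silico
    validation with planted DMRs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    Sequencing, LongRead, HiddenMarkovModel
RoxygenNote: 7.3.3
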
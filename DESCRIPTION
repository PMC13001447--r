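Package: epimutMA
Title: Epimutation Rate Estimation from Mutation Accumulation Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying spontaneous cytosine methylation changes
    (epimutations) along haploid mutation accumulation pedigrees, modelled
    on experiments with the filamentous fungus Neurospora crassa. Provides
    forward simulation of methylomes along a pedigree with heritable
    gain/loss dynamics restricted to chromatin domains, per-cytosine
    methylation state calling with a binomial-emission hidden Markov model,
    100-bp differentially methylated region (DMR) segmentation, pairwise
    divergence statistics for methylation states, ChIP peak presence/absence
    and binned read counts, least-squares fitting of a haploid two-state
    neutral epimutation accumulation model with multi-start optimisation and
    cluster bootstrap intervals, model comparison against null and logistic
    alternatives, and genomic enrichment analyses of DMR placement across
    chromatin domains and sequence annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
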
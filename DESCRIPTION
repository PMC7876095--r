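Package: replifork
Title: Replication Dynamics of HR-Restarted Forks at Programmed Barriers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-cell Monte Carlo simulation of locus replication with
    directional fork barriers and homologous-recombination (HR) fork
    restart, aggregation of cell ensembles into polymerase-usage profiles,
    computation of polymerase usage sequencing (Pu-seq) traces from binned
    strand-specific ribonucleotide counts, line-search estimation of
    barrier parameters (arrest efficiency, restart delay, restart offset)
    against observed traces, and a synthetic Pu-seq count generator so the
    whole analysis runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    yaml,
    jsonlite,
    signal,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Sequencing, Coverage, DNAReplication
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'traces.R'
    'simulate.R'
    'fitting.R'
    'locus-model.R'
    'oracle.R'
    'synthetic.R'
    'pipeline.R'
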
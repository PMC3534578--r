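Package: pauseTrace
Title: Detecting Sequence-Dependent Transcriptional Pauses from RNA and
    Protein Number Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A delayed stochastic simulator of prokaryotic transcription and
    translation at nucleotide and codon resolution, with sequence-dependent
    transcriptional pause sites, together with the statistical machinery to
    detect the presence of a pause site, classify pause kinetics, and estimate
    the pause location from time series of mRNA and protein numbers. Includes
    a generic delayed stochastic simulation engine with arbitrarily
    distributed release delays, a full reaction-level model of gene expression
    (initiation, stepwise elongation with pausing, arrests, editing,
    premature termination, pyrophosphorolysis and polymerase traffic; stepwise
    translation with codon-specific rates, ribosome traffic,
    back-translocation, drop-off and trans-translation), windowed-mean
    hypothesis tests for pause detection, a 10-dimensional time-series feature
    set with hierarchical clustering and random-forest classification, and a
    density-overlap approximate likelihood estimator of pause-site position
    with bootstrap confidence intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    withr,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
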
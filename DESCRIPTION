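Package: segbound
Title: Signal-Detection Scoring of Boundary-Segmentation Click Experiments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores real-time segmentation ("click") responses against
    hierarchical expert-defined boundary regions on a recording's
    timeline.  Provides the full analysis chain used in auditory
    boundary-perception studies: half-open timeline partitions at two
    hierarchy levels, hit and false-alarm rates per region, the d'
    sensitivity index with extreme-rate correction, promptness and
    cumulative promptness scores, pooled per-region click densities and
    histograms, a musicianship composite, and the accompanying
    nonparametric statistical battery (Kruskal-Wallis with eta-squared,
    exact Wilcoxon tests with configurable pairing schemes, a
    Hartigan-type dip test for unimodality with bootstrap p values, a
    raga-by-level factorial ANOVA with partial eta-squared confidence
    intervals, and correlation screens).  A synthetic-listener generator
    emulates cohorts of segmenting listeners so that every stage of the
    pipeline can be exercised and validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nortest,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
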
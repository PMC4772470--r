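Package: burstDE
Title: Distribution-Based Differential Expression for Single-Cell RNA-Seq
    via the Transcriptional Bursting Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression analysis for single-cell RNA-seq that
    compares the full per-gene read-count distribution between two groups of
    cells rather than only the mean. Genes are tested with the two-sample
    Cramer-von Mises criterion, the Kolmogorov-Smirnov test, or a Monte-Carlo
    Poisson-Beta likelihood-ratio test, and the two-state (telegraph)
    transcriptional bursting model is fitted per gene by the method of
    moments or by a collapsed Gibbs sampler with slice sampling, so that
    changes can be reported in biologically interpretable terms: burst size,
    burst frequency, duty cycle, mean expression and autocorrelation time.
    Includes median-of-ratios size-factor normalization, empirical and
    Benjamini-Hochberg significance thresholds, and a synthetic benchmark
    suite (sensitivity grids, null-control calibration, mean-preserving
    variance changes, dropout simulation).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
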
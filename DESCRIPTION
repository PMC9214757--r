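Package: hicogeny
Title: Hi-C Contact-Map Analysis for Germline Chromatin Architecture
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of binned Hi-C contact matrices along a developmental
    series: iterative correction (ICE) balancing, contact-probability decay
    curves and their log-log slopes, A/B compartment calling from the first
    principal component of the observed/expected correlation matrix,
    saddle-plot compartment strength, directionality-index and hidden Markov
    model TAD calling, insulation scores, focal loop detection with local
    expected models and Poisson significance, quantile-normalised matrix
    deconvolution, sliding-window conserved-region detection, and Fisher
    enrichment with Benjamini-Hochberg control. Includes a synthetic
    contact-map generator with planted compartments, TADs, loops and bin
    biases for validation against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
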
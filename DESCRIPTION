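Package: stealthmx
Title: Stealth-Multiplet Probabilities for Sample-Multiplexed Droplet
    Single-Cell Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-form probabilities of the four multiplet classes
    (homogeneous stealth, partial stealth, multilabelled, unlabelled)
    arising in sample-multiplexed droplet single-cell RNA-seq under a
    Poisson cell-loading model, together with the true singlet ratio.
    Provides inverse estimation of the average labelling efficiency and
    the droplet loading rate from observed demultiplexing count tables,
    a seeded Monte-Carlo droplet simulator that serves both as an
    independent oracle for the closed forms and as a synthetic-data
    generator, and a concordance auditor that classifies droplets from
    two paired demultiplexing call sets to quantify partial stealth
    multiplets, including two-Gaussian score thresholding for
    double-positive multiplet calling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
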
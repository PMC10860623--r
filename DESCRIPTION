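Package: betaherit
Title: Heritability of Sensorimotor Beta Events and Aperiodic Neural Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying the heritability of
    resting-state sensorimotor MEG phenotypes in sibling cohorts. Generates
    synthetic two-channel sensor recordings with a 1/f aperiodic background and
    intermittent ~20 Hz beta bursts, plus sibling-structured phenotypes with a
    known additive genetic variance share. Parameterizes power spectra into
    aperiodic (offset, exponent) and periodic components, extracts time-resolved
    beta events from Morlet amplitude envelopes by percentile thresholding, and
    estimates narrow-sense heritability with a family-block variance-component
    maximum-likelihood model, family-label permutation significance testing and
    Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
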
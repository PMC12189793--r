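Package: toiseg
Title: Optimal Times-of-Interest Segmentation and Normalization of
    Intervention-Perturbed Perfusion Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Robust analysis of microvascular perfusion recordings (for
    example laser speckle contrast imaging traces) that are perturbed by
    experimental interventions. Provides exact penalized changepoint
    detection (PELT) with a least-squares piecewise-linear segment cost,
    an algorithm that turns detected changepoints plus experimenter
    markers into optimal times of interest (TOIs) and explicit transition
    windows that isolate intervention artifacts, reference-state
    z-normalization of signals and their piecewise-linear approximations,
    rank-based individual and group comparisons (Kruskal-Wallis omnibus
    test and Dunn pairwise post hoc with family-wise correction), a
    synthetic-cohort generator with AR(1) noise and boundary artifact
    bursts, and an end-to-end pipeline with tabular input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    readxl,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
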
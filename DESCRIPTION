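Package: patchmorph
Title: Intrinsic Excitability and Dendritic Morphometry from Current-Clamp
    Recordings
Version: 0.1.0
Authors@R:
    person("Patchmorph", "Developers", email = "patchmorph@example.org",
           role = c("aut", "cre"))
Description: Feature extraction for whole-cell current-clamp recordings
    (resting membrane potential, input resistance, membrane time constant,
    sag ratio, action-potential waveform features, firing-rate curves),
    morphometric and Sholl analysis of SWC neuronal reconstructions
    (centrifugal branch order, dendritic complexity index, soma area),
    group-comparison statistics (pooled two-sample t-tests from raw data or
    printed summary statistics, two-way ANOVA with optional repeated
    measures, Sidak adjustment), and a synthetic-data module with a
    leaky-integrate-and-fire cell simulator and a random dendritic-tree
    generator with bookkept ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
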
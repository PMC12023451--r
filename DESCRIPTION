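Package: ephysflow
Title: Patch-Clamp Intrinsic Excitability, Synaptic Event Detection, and
    Go/No-Go Behavioural Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for whole-cell patch-clamp recordings and
    olfactory go/no-go behaviour. Extracts passive and active membrane
    properties (series resistance with quality control, membrane capacitance
    from the charge-voltage relation, input resistance, membrane time
    constant, sag, F-I gain, rheobase, phase-plot action-potential features)
    from current- and voltage-clamp step protocols; detects and characterises
    spontaneous postsynaptic currents with amplitude and kinetics acceptance
    rules; compares event-property distributions between groups with a
    per-cell balanced bootstrap of cumulative probability distributions and a
    permutation Kolmogorov-Smirnov test; and scores go/no-go sessions with
    block performance, learning criterion, and ROC/AUC analysis with
    Hanley-McNeil standard errors. Includes ground-truth-labelled synthetic
    generators for membrane responses, spiking, synaptic event trains, and
    behavioural sessions so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
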
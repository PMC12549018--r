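Package: brainfluid
Title: Whole-Brain Network Simulation and Complexity Metrics of Consciousness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates networks of Montbrio-Pazo-Roxin neural masses coupled
    through a structural connectome with conduction delays and additive noise,
    and computes the dynamical metrics used to characterize conscious and
    anesthetized brain states: a simulated perturbational complexity index
    built on Lempel-Ziv complexity, dynamic functional connectivity fluidity,
    neuronal-avalanche functional repertoires with branching ratios, and the
    global activation potential. Ships synthetic connectome and EEG
    generators, a parameter-space sweep over global coupling and noise
    intensity, an EEG bootstrap metric pipeline, and single-feature linear
    classification of brain states.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
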
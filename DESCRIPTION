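Package: plvnet
Title: Time-Frequency Phase Synchrony Brain Networks from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds functional brain networks from multichannel EEG using a
    reduced-interference Rihaczek time-frequency distribution with a
    Choi-Williams kernel, time-frequency phase-locking values between channel
    pairs, density-thresholded binary networks, graph measures (degree,
    clustering, characteristic path length, local efficiency), small-worldness
    against degree-preserving Markov-chain null ensembles, and nonparametric
    condition comparisons with a first-principles Wilcoxon rank-sum test.
    Includes a synthetic coupled-oscillator generator with analytic von Mises
    phase-locking ground truth and reference graph constructions for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
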
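Package: stimnet
Title: Network-Mediated Activation Analysis for Intracranial Stimulation
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether resting-state functional connectivity
    predicts where direct electrical stimulation changes spectral power in
    intracranial EEG. Implements multitaper coherence and high-frequency
    broadband amplitude-envelope networks, stimulation-evoked pre/post band
    power contrasts with artifact-channel rejection, the distance-controlled
    permutation regression statistic ("network-mediated activation", NMA),
    and group-level analyses (white-matter trend permutation test, hub
    terciles, per-frequency NMA profiles with FDR control). A synthetic-data
    generator plants known coherence structure and connectivity-to-power
    effects so every stage of the pipeline is verifiable against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
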
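Package: mupool
Title: Motor Unit Pool Simulation of Muscle Force and Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Biophysical simulation of a motor neuron pool, twitch-based
    muscle force generation with nonlinear fusion, and surface
    electromyogram synthesis from current-tripole fiber action
    potentials in a cylindrical muscle. Includes a sensitivity-analysis
    pipeline for patterns of motor unit loss (largest, smallest, or
    unrestricted removal) under onion-skin and reverse onion-skin firing
    strategies, quantifying muscle strength, force variability, and the
    EMG-force relation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
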
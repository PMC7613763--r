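Package: cardiopore
Title: Simulation and Analysis of Electroporation-Mediated Intracellular-Like
    Recordings from HD-MEA Cardiomyocyte Cultures
Version: 0.1.0
Authors@R:
    person("Cardiopore", "Developers", email = "cardiopore@example.org",
           role = c("aut", "cre"))
Description: Tools to turn raw high-density microelectrode-array (HD-MEA)
    voltage traces of cardiomyocyte cultures into electrophysiological
    endpoints. Includes a phenomenological simulator of spontaneously beating
    cardiomyocytes coupled to planar electrodes (extracellular field
    potentials, electroporation-induced intracellular-like signals, membrane
    pore resealing, amplifier offset artifacts), beat detection and
    waveform classification (extracellular versus intracellular-like),
    action-potential feature extraction (AP amplitude, APD90, depolarization
    time, field-potential amplitude, culture synchrony), electroporation
    yield statistics across repeated porations, and drug-response
    quantification with an exact Mann-Whitney U test. A command-line
    interface orchestrates simulate / analyze / report runs with full seed
    determinism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
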
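Package: c14pop
Title: Radiocarbon Date Frequencies as Population Proxies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs relative population histories from radiocarbon
    date frequencies. Provides calibration against IntCal-style curves,
    summed probability distributions (SPDs) on an annual calendar grid
    with moving-average smoothing, segmented log-link GLM breakpoint
    detection, exponential and five-parameter Richards-logistic null
    models, a Monte-Carlo significance test that flags demographic booms
    and busts against a simulation envelope and reports a global p-value,
    power-law taphonomic correction, rank correlation between SPDs, and a
    synthetic-data generator with known demographic ground truth so every
    stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    datasets,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
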
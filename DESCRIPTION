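Package: phipchip
Title: Reaction-Transport and Spin-Dynamics Modelling of Microfluidic
    Parahydrogen-Induced Polarization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale models of continuous-flow parahydrogen-induced
    polarization (PHIP) on a membrane-fed microfluidic chip. Provides a
    reduced-order plug-flow model of hydrogen permeation through a PDMS
    membrane into the flowing liquid coupled to hydrogenation kinetics, a
    density-matrix simulator of singlet-to-carbon-13 polarization transfer
    (purge pulse plus S2hM echo trains) in [1-13C]fumarate, the NMR
    quantification chain (peak integration, concentration referencing,
    signal-to-noise, enhancement factor, percent polarization and yield),
    and deterministic synthetic-spectrum generators so every pipeline is
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
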
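Package: liposhg
Title: Adsorption and Transport of SHG-Active Dyes at Liposome Surfaces
Version: 0.1.0
Authors@R:
    person("liposhg", "developers", email = "liposhg@example.org",
           role = c("aut", "cre"))
Description: Analysis of second harmonic generation (SHG) spectroscopy
    experiments probing molecular adsorption and translocation at colloidal
    liposome surfaces. Fits adsorption isotherms with a modified Langmuir
    model that accounts for bulk depletion of the adsorbate, extracts
    membrane transport (flip-flop) times from field-domain single-exponential
    fits of SHG time traces, calibrates the hyper-Rayleigh scattering
    background, and derives adsorption free energies, lipids per adsorption
    site, and signal per surface coverage. Includes a seeded synthetic
    experiment generator with a two-leaflet population model so that the
    entire pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
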
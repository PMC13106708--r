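Package: diatomsync
Title: Phytochrome-Gated Collective Wobbling in Diatom Populations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for light-driven collective
    "wobbling" in populations of elongated sinking diatoms such as
    Phaeodactylum tricornutum. Provides a two-state phytochrome
    photostationary-state model for multiband illumination protocols, a
    weakly coupled phase-oscillator (Kuramoto) population simulator with
    photoreceptor-gated coupling and pulsed-light forcing, a geometric
    laser-diffraction forward model producing 32-bin size-class volume
    concentrations and the VD1/VD2 Ratio orientation proxy, a two-band
    chlorophyll autofluorescence observation model, prominence-gated
    Gaussian spectral-peak characterization (Pk/FWHM amplitudes,
    entrainment indices), and config-driven experiment runners for
    wavelength scans, red:blue mixing, pulsed-light entrainment and
    fluorescence assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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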
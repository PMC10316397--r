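Package: porepi
Title: Pi-Helix Pore States, Hydration and Conductance of Nav Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how pi-helix content of the pore-lining S6 helices
    of voltage-gated sodium (Nav) channels relates to pore hydration, ion
    permeation free energy and single-channel conductance class. Provides a
    Brownian-dynamics generator for ions and waters in a cylindrical pore
    under an axial potential of mean force and an applied transmembrane
    voltage; permeation-event detection and conductance estimation with
    replicate statistics; axial water-density profiles and hydration calls;
    well-tempered metadynamics on the ion axial coordinate with free-energy
    reconstruction and barrier extraction; ideal alpha/pi helix building,
    secondary-structure assignment and pore-facing register-shift analysis;
    and a classifier mapping per-subunit alpha/pi composition to conductance
    class (fully conductive, subconductance, nonconducting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
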
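Package: hdospec
Title: Solute-Affected Water Analysis from HDO Difference Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for isolating and characterising solute-affected water from
    FTIR spectra of HDO (semi-heavy water) solutions. Implements the two-state
    difference model that extracts the molar absorption spectrum of water
    perturbed by a solute from a molality series together with the affected
    number N, a removal-maximising decomposition of ternary (two-solute)
    affected spectra into pure-component shares plus a changed-affected
    residual, conversion of OD-stretch band contours into intermolecular
    oxygen-oxygen distance distributions via an empirical wavenumber-distance
    correlation, an ATR difference-spectra screen for direct solute-solute
    interactions, and post-processing of hydration-cluster geometries into
    O...O distance statistics. Includes seeded synthetic-data generators that
    invert each analysis stage for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    pracma,
    jsonlite,
    yaml,
    bio3d
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
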
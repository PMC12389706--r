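Package: padMC
Title: Monte Carlo Dosimetry of High-Z Doped Hydrogel Radiotherapy Pads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled photon-electron Monte Carlo transport through a
    hydrogel shielding pad placed on a four-layer skin phantom (epidermis,
    dermis, subcutaneous fat, muscle, water backing). Builds composite pad
    materials (alginate, chitosan or cellulose hydrogels doped with Bi2O3 or
    ZnO), evaluates mixture-rule photon attenuation from embedded per-element
    partial cross-section tables, transports electrons by condensed-history
    stepping (Bethe collision stopping, Highland multiple scattering, 1/k
    bremsstrahlung), tallies per-layer energy deposition with batch standard
    errors, and sweeps the full pad material x thickness x beam grid to derive
    shielding metrics and pad-layer heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
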
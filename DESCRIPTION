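Package: neholo
Title: Near-Field Electromagnetic Holography for Microelectrode Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs electromagnetic field estimates at a chosen depth
    plane inside neural tissue from planar microelectrode-array voltage
    recordings, by angular-spectrum (k-space) back-propagation with a smooth
    spatial-frequency filter. Provides electric-field estimation from
    potentials, magnetic-field estimation via the wave-vector cross product,
    Poynting energy-flow vectors, energy source density and dissipation maps,
    Papoulis-Gerchberg band-limited interpolation for virtual electrodes, a
    quasi-static forward simulator for synthetic ground truth, and wavelet
    phase-semblance tools for validating reconstructions against recorded
    time series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
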
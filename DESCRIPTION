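Package: bmtsim
Title: Simulation and Morphometry of Five-Protofilament Bacterial Microtubules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds helical tube-lattice models of BtubA/B bacterial
    microtubules, simulates cryo-electron tomography of them (projection
    tilt series, contrast transfer function, missing wedge, weighted
    backprojection), and analyses the simulated volumes the way the
    protofilament number of these tubes was established: Fourier-Bessel
    layer-line indexing of power spectra, cross-section diameter and
    left-right asymmetry morphometry, and constrained subtomogram
    averaging. All data are generated internally; an atomic heterodimer
    template can optionally replace the coarse-grained subunit.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    bio3d,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
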
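Package: cestkit
Title: Simulation and Evaluation of CEST MRI Saturation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for chemical exchange saturation transfer (CEST) MRI
    experiments run entirely in silico: construction and serialization of
    pre-saturation pulse trains (APTw sinc-Gauss trains, WASABI rectangular
    pulses), Bloch-McConnell simulation of multi-pool exchange environments
    including a semisolid magnetization transfer pool via piecewise-constant
    matrix-exponential propagation, evaluation of Z-spectra into MTRasym
    curves and WASABI B0/B1 field maps, and a synthetic five-tube digital
    phantom for end-to-end pipeline runs without measured data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
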
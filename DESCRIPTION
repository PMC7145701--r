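Package: nascentTrack
Title: Single-Molecule Kinetics of Cap-Dependent Translation from
    Nascent-Peptide Antibody Binding
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule TIRF assays that
    track eukaryotic cap-dependent translation through fluorescent antibody
    binding to nascent N-terminal epitope tags. Provides a ground-truth
    stochastic simulator of per-mRNA initiation, epitope exposure, antibody
    recognition and release timelines, synthetic fluorescence traces and
    TIRF-like movie stacks; an imaging pipeline (drift correction,
    background subtraction, spot detection, sub-pixel 2D Gaussian
    localization, aperture photometry); change-point based step calling
    that converts traces into binding and dissociation events; and kinetic
    model fitting: double-exponential antibody recognition, shifted
    (3-parameter) log-normal first-arrival distributions with bootstrap
    errors, log-normal dwell times, and derived initiation and peptide
    chain elongation rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    minpack.lm,
    survival,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
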
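Package: timesig
Title: Simulation and Inverse Analysis of Transient Induced Molecular
    Electronic Spectroscopy Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward model and inverse analysis for transient induced
    molecular electronic spectroscopy (TIMES), a label-free microfluidic
    technique that detects protein-ligand binding through the transient
    current induced on an electrode by dipole reorientation of molecules
    arriving at its surface. Implements the signal physics (Boltzmann
    surface partition, one-dimensional diffusion across the channel
    half-height, Langmuir adsorption-desorption kinetics, convolution
    with a per-molecule induced-charge kernel), a seeded synthetic
    experiment generator that stands in for the instrument, and the
    inverse analyses: Tikhonov-regularised kernel deconvolution,
    exponential surface-dwell-time fitting versus wall shear stress, and
    per-timepoint dissociation-constant extraction from four-condition
    mixture designs with histogram-mode estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
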
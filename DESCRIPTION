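Package: stiffsim
Title: Diffusion-Reaction Modelling of Enzyme-Mediated Hydrogel Stiffening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates tyrosinase-mediated stiffening of PEG-peptide hydrogels
    by coupling one-dimensional Fickian enzyme transport into a swollen slab
    with Michaelis-Menten conversion of network-immobilized tyrosine residues
    into DOPA-dimer crosslinks. Provides the hydrogel structural chain
    (swelling ratios, molecular weight between crosslinks, mesh size,
    Lustig-Peppas in-gel diffusivity), an analytic Fourier-series and a
    Crank-Nicolson finite-difference slab solver, Michaelis-Menten kinetics
    with optional substrate inhibition and nonlinear least-squares fitting,
    the Lambert-W closed form of the integrated rate law for space- and
    time-resolved product formation with an independent ODE oracle, power-law
    analysis of the shear modulus versus polymer volume fraction correlation,
    seeded synthetic-data generators, CSV/YAML/JSON input-output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
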
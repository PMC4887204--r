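Package: morphograd
Title: Morphogen Gradient Formation from Diffusion, Binding and Clearance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of morphogen gradient formation
    in early embryos. Implements fluorescence correlation spectroscopy (FCS)
    and cross-correlation (FCCS) model evaluation and Levenberg-Marquardt
    curve fitting to extract particle numbers, triplet-state parameters and
    diffusion coefficients; dissociation-constant estimation from FCCS
    concentration data (regression and log-Kd histogram estimators);
    ligand-receptor mass-action binding equilibrium, effective diffusion
    coefficients and source-sink gradient-length theory; a 3D slab
    random-walk simulation of hindered diffusion among cylindrical cell
    obstacles with quasi-equilibrium binding; a 1D particle simulation of
    gradient formation with continuous production and first-order
    degradation, with a closed-form reaction-diffusion steady-state oracle;
    fluorescence-image gradient profiling with exponential decay-length
    fitting; exponential clearance-rate fitting for protein decay time
    courses; and synthetic-data generators for all of the above so every
    pipeline stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    MASS,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
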
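Package: idpfel
Title: Free-Energy Landscapes of Intrinsically Disordered Peptides from
    Bias-Exchange Metadynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs conformational free-energy landscapes of
    intrinsically disordered peptides from bias-exchange metadynamics
    data: microstate binning of collective-variable (CV) trajectories,
    self-consistent weighted-histogram (WHAM) free-energy estimation from
    per-replica one-dimensional bias potentials, Boltzmann-weighted
    ensemble observables sliced by free energy, and a two-state
    Gibbs-Helmholtz model of temperature-induced structuring. Also
    provides the accompanying experimental-biophysics layer (empirical
    hydrodynamic radii, compaction index, pulsed-field-gradient NMR
    diffusion fits, Stokes-Einstein, circular-dichroism mean-residue
    ellipticity) and synthetic-data generators with known ground truth
    (multi-basin CV landscapes, biased replica sampling, toy peptide
    conformations, diffusion decays, restrained energy traces).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
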
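Package: crowdsolv
Title: Analysis of Molecular Crowding Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing molecular dynamics studies of molecular
    crowding in small-crowder solutions (tetraethylene glycol, PEG-4, with
    water and a model protein). Builds solution compositions for a target
    concentration with unit conversions and crowder volume fractions;
    estimates translational diffusion from mean-squared displacements with
    Yeh-Hummer and solute-size finite-size corrections; estimates shear
    viscosity by the non-equilibrium periodic-perturbation (cosine
    acceleration) method and the equilibrium Einstein-Helfand
    pressure-tensor method; provides the Enskog hard-sphere reference for
    diffusion decline versus crowder volume fraction; and computes
    structural observables (RMSD/RMSF, non-normalised solvation RDFs and
    coordination numbers, geometric hydrogen bonds by molecular class,
    pairwise Coulomb and Lennard-Jones interaction energies, and
    Shrake-Rupley solvent accessible surface area split into hydrophilic
    and hydrophobic parts by partial charge). Synthetic-data generators
    with known ground truth (Brownian particles, cosine shear flows,
    Ornstein-Uhlenbeck pressure series, toy solvated configurations)
    support end-to-end validation of every estimator.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
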
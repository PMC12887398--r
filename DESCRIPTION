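Package: stemopen
Title: Quantitative Analysis of Protein-Driven RNA Hairpin Remodeling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for biophysical studies of protein-induced
    remodeling of small RNA hairpins: single-site equilibrium binding fits
    with ligand depletion for fluorescence anisotropy and FRET titrations,
    two-state van't Hoff thermal-melt analysis with derivative-based melting
    temperatures and dose-dependent transition amplitudes, NMR amide
    chemical-shift-perturbation mapping, structural collective variables
    (Kabsch superposition RMSD, switching-function coordination numbers,
    base-pair distances), a well-tempered metadynamics engine on toy
    collective-variable-space potentials with an overdamped Langevin
    sampler, and free-energy-surface reconstruction with watershed basin
    analysis. Includes seeded synthetic-data generators for every input so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    jsonlite,
    minpack.lm,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
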
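Package: integrinmech
Title: Elastic-Network, Free-Energy and Membrane Analyses for
    Transmembrane Helix Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for studying the mechanics of integrin
    transmembrane-domain clustering: C-alpha elastic-network normal-mode
    analysis with hinge/domain detection, free-energy profile estimation
    from repeated steered-pulling work traces via the Jarzynski equality
    and its second-order cumulant expansion, lipid bilayer density and
    thickness profiling along an inter-monomer axis, truncated non-bonded
    group-group interaction energies, and the closed-form diffusion and
    force-feasibility arithmetic used to choose steering speeds and assess
    cytoskeletal energy input. Includes seeded synthetic-data generators
    (hinged two-domain structures, membrane patches with known density
    contrast, overdamped-Langevin pulling traces on a prescribed
    free-energy profile) so every estimator can be validated against
    ground truth, plus a command-line interface over all analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
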
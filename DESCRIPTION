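Package: calcarb
Title: Calcium-Carboxylate Association and Amorphous Calcium Carbonate
    Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for refining Lennard-Jones descriptions of the
    Ca2+-carboxylate interaction (Lorentz-Berthelot mixing, A/B repulsion
    coefficients, stepwise sigma scaling), for converting one-dimensional
    free-energy profiles along an ion-pair distance into association
    constants and free energies of association, and for structural
    analysis of ion-cluster formation in periodic trajectories: radial
    and angular distribution functions, coordination numbers, local mass
    density, Shrake-Rupley solvent-accessible surface area,
    coordination-shell cluster detection, and Tanimoto-based
    configuration similarity. Includes seeded synthetic-data generators
    and a one-dimensional well-tempered metadynamics simulator for
    validating the free-energy pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
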
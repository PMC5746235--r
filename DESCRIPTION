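Package: vortexsim
Title: Multi-Species Bacterial Colony Simulation on Vectorizable Random Lattices
Version: 0.1.0
Authors@R:
    person("Gilad", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Finite-volume simulation of cooperating bacterial colonies
    (Paenibacillus vortex transporting Escherichia coli through an antibiotic
    environment, optionally with a carbon-fixing microalga) using coupled
    nonlinear reaction-diffusion equations with a global builder/explorer
    phase switch. The spatial discretization is a Vectorizable Random Lattice:
    one node drawn per cell of a rectangular reference lattice subject to
    per-axis minimum-distance constraints, with Voronoi/Delaunay finite-volume
    weights. Includes forward-Euler and Crank-Nicolson (Gauss-Seidel split)
    time integrators, mass-conservation diagnostics, the scenario catalogue
    behind the ring-pattern experiments (single species, mixed colony, two
    colonies, antibiotic half-plane, three species, sensitivity sweeps), and
    CSV/VTK/JSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
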
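Package: capflow
Title: Discrete Red Blood Cell Tracking and Blood Flow Simulation in
    Microvascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates blood flow in microvascular network graphs with
    individually tracked red blood cells (RBCs). Vessel resistances follow
    Poiseuille's law corrected for the Fahraeus-Lindqvist effect, nodal
    pressures are obtained from a sparse mass-balance solve, and RBCs are
    advected discretely with phase separation at divergent bifurcations
    (empirical logit law for mother vessels of 10 micrometres and above, a
    pressure-force bifurcation rule below). Includes a seeded generator of
    synthetic cortical capillary networks with penetrating arterioles and
    venules, time-averaged flow-field analysis of well-balanced capillary
    bifurcations, in-silico capillary dilation experiments, and spatial
    statistics of well-balanced bifurcations (analysis layers, nearest
    neighbour distances, path lengths to penetrating vessels, tissue
    distance grids).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    e1071,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
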
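Package: proteonet
Title: Coupled Amyloid-Beta and Tau Heterodimer Dynamics on Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a coupled two-protein (amyloid-beta
    and tau) heterodimer aggregation model on weighted brain-connectome
    graphs and synthetic lattices. Provides closed-form stationary states,
    regime classification and Jacobian eigenvalue stability analysis of the
    homogeneous kinetics; weighted graph Laplacian and transneuronal damage
    adjacency assembly with GraphML input and output; stiff integration of
    the network reaction-diffusion equations coupled to a first-order
    neuronal damage model; one-dimensional travelling-front simulation with
    the linearized (pulled) front-speed catalogue; and disease-progression
    observables such as toxic load, onset time, invasion window and
    saturation curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    Matrix,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
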
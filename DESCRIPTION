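Package: pcmhill
Title: Parallel Cluster Model of Myosin-II Ensembles and the Hill
    Force-Velocity Relation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanics and stochastic kinetics of a parallel cluster of
    myosin-II motors sharing a constant external load: per-state strain,
    elastic energy and Boltzmann power-stroke occupancy, catch-bond
    unbinding rates, an effective one-step master equation in the bound
    motor count with its stationary distribution and mean bound-ensemble
    velocity, and a seedable Gillespie trajectory simulator. Force-velocity
    curves generated by the molecular model are fitted with the hyperbolic
    Hill muscle relation, and the macroscopic Hill muscle model
    (contractile, series-elastic and parallel-elastic components with
    pennation geometry) is provided alongside.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
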
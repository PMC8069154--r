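Package: actinf
Title: Discrete-State Active Inference and the Information Geometry of
    Belief Updating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates perception, planning and learning in partially
    observed Markov decision processes (POMDPs) under active inference,
    where state estimation is a descent on variational free energy, and
    under a natural-gradient variant that preconditions the descent with
    the inverse Fisher information metric.  Provides the Fisher-Rao
    geometry of the categorical simplex (metric, information distances,
    path lengths, geodesics), simulated local field potentials from the
    rate of change of the log-belief (voltage) code, Dirichlet learning
    of likelihood and transition mappings, builders for a T-Maze
    foraging task and an abstract-rule surrogate task, and cohort
    experiments that compare the information length of belief updating
    between the two schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
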
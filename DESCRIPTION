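Package: cpgwalk
Title: Bilateral Half-Center CPG Neuromusculoskeletal Simulation of Cat
    Hindlimb Treadmill Locomotion
Version: 0.1.0
Authors@R:
    person("cpgwalk", "maintainers", email = "cpgwalk@example.org",
           role = c("aut", "cre"))
Description: Simulates treadmill locomotion of the cat hindquarters with a
    planar seven-link musculoskeletal model driven by a pair of two-level
    half-center central pattern generators (rhythm-generator and
    pattern-formation layers, commissural C1/V3 pathways, and motoneuron
    pools) built from activity-based neuron models with a persistent
    sodium current. Includes Hill-type muscle actuation, velocity, length
    and force afferent feedback, viscoelastic belt contact with flat,
    per-step randomized and hole ground profiles, CMA-ES optimization of
    pattern-formation-to-motoneuron weights and feedback gains, and
    frozen-variable nullcline analysis of the fast/slow rhythm-generator
    dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
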
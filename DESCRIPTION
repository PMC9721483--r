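Package: rloed
Title: Reinforcement Learning for D-Optimal Design of Dynamic Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for designing maximally informative time-course experiments
    on dynamic biological models via the Fisher information matrix. Implements
    a chemostat model of auxotrophic bacterial growth with forward
    log-sensitivity propagation and accumulation of the Fisher information
    matrix as a compiled ODE system, D-optimality scoring, classical designers
    (greedy one-step-ahead optimisation and full-horizon model predictive
    control), and reinforcement-learning designers: neural fitted Q-learning
    over a discretised input grid and a recurrent twin-delayed deterministic
    policy-gradient (TD3) agent over continuous inputs, trainable at a fixed
    parametrisation or over a prior distribution of parameters. Evaluation
    pipelines score designs by value-function accuracy and by downstream
    parameter-inference quality on simulated noisy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: deSolve, jsonlite, minpack.lm, stats, utils, yaml
Suggests: optparse, testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
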
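Package: mapmpc
Title: Genetic-Algorithm Model Predictive Control of Mean Arterial Pressure
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop simulation and controller suite for regulating mean
    arterial pressure (MAP) by sodium-nitroprusside (SNP) infusion. Provides a
    dead-time transfer-function patient model with exact zero-order-hold
    discretization, a receding-horizon model predictive controller whose move
    optimization is performed by a real-coded genetic algorithm, baseline
    controllers (Ziegler-Nichols PID, particle-swarm MPC, deterministic
    grid-search MPC), a viscoelastic mass-spring-damper model of the heart
    muscle and measurement chain, IAE/ISE/MSE performance indices, and a
    scenario runner for step-tracking, horizon-sweep, disturbance-rejection
    and controller-comparison experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    signal,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
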
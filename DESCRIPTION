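Package: wardrl
Title: Hybrid Model-Based/Model-Free Reinforcement Learning for Simulated Care Wards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A brain-inspired hybrid reinforcement-learning framework for
    autonomous care decisions in a simulated cerebral-palsy ward. Combines a
    model-free tabular Q-learner with a model-based planner on an empirically
    learned transition model, arbitrated step-by-step by a variance-driven
    meta-controller, extended with counterfactual action scans, a symbolic
    clinical rule layer, and a hardware-level safety reflex. Ships a
    deterministic multi-agent ward simulator, a synthetic patient generator,
    baselines (model-free only, model-based only, a small neural Q-learner),
    ablations, and an evaluation harness (regret, convergence, falls, sample
    efficiency, composite scorecard) with tidy outputs and ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
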
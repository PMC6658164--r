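Package: banditfit
Title: Q-Learning Analysis of Dynamic Two-Armed-Bandit Choice Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reinforcement-learning analysis of mouse choice
    behavior in dynamic two-armed-bandit and progressive reversal tasks.
    Provides seeded generators for task environments and Q-learning agent
    cohorts with known ground-truth parameters, maximum-likelihood fitting of
    a six-variant Q-learning model family (learning rates for positive and
    negative outcomes, softmax inverse temperature, choice bias, win-stay /
    lose-switch penalty terms, uncertainty-based exploration), dynamic- and
    steady-state segmentation of block choice data, win-stay / lose-switch
    and reward-rate metrics, fitted action-value block profiles, and a
    group-level inference pipeline (mixed-design and between-groups ANOVAs,
    Bonferroni post-hoc tests, and a permutation control) for detecting
    dissociations between action-selection and value-learning deficits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    lhs,
    car,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
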
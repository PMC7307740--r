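Package: crlexes
Title: Embodied Control-Based Reinforcement Learning Agents in an
    Anti-Coordination Game
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates dyads of two-layer cognitive agents playing the
    "Battle of the Exes", a repeated embodied anti-coordination game with a
    high- and a low-value reward spot. Each agent couples a pre-wired
    Braitenberg-style reactive controller (reward seeking and collision
    avoidance) with an actor-critic temporal-difference learner that picks a
    round-level action and gates the reactive behaviors through an inhibitor
    function. The package provides the continuous-time arena, a discrete
    (ballistic) resolution mode, layer-ablated variants, tidy round logs,
    the coordination metrics used to study convention formation (efficiency,
    fairness, surprisal-based stability, reliance on the adaptive layer),
    experiment drivers for condition grids, ablations and payoff sweeps,
    condition-comparison statistics, and ggplot2 figures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
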
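Package: pollinet
Title: Agent-Based Simulation of Bee Foraging and Plant-Pollinator Networks
    over Deforestation Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the foraging flights of a community of bee species over
    binary forest/open landscapes using a correlated random walk with
    per-species energy budgets, and records flower visitation as a bipartite
    bee-by-plant interaction matrix. Includes a fractal neutral landscape
    generator with nested (sequential) habitat-loss gradients, FRAGSTATS-style
    class metrics (PLAND, AREA, SHAPE, CONNECT), bipartite network descriptors
    (connectance, NODF nestedness, H2' complementary specialization, network
    size and asymmetry), and an experiment driver with single-predictor GLM
    and Spearman correlation analyses of the simulated networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rlang,
    withr,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    ggplot2
Suggests:
    vegan,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
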
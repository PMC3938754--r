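Package: proteocost
Title: Proteostatic Energy Cost, Selection, and the Evolution of Protein Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the chemical energy a cell spends maintaining its proteome
    through steady-state protein turnover (synthesis, folding, unfolding,
    degradation) and treats the energy left over for reproduction as fitness.
    From this cost function the package derives per-protein fitness cost
    coefficients, selection coefficients for mutations that change abundance,
    stability, turnover, length, or synthesis cost, and Kimura fixation
    probabilities. A fixation-weighted transition kernel over a folding
    free-energy grid, driven by a bi-Gaussian distribution of mutational
    stability effects, is iterated to the mutation-selection equilibrium
    distribution of protein stabilities, with a stochastic origin-fixation
    simulator as an independent cross-check and a synthetic proteome
    generator for whole-proteome exercises.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
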
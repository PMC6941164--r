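Package: vfamethane
Title: Predict Enteric Methane Yield of Cattle from Ruminal Volatile Fatty Acids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Develops and validates equations that predict the enteric methane
    yield (g CH4 per kg dry-matter intake) of cattle from the molar proportions
    of acetate, propionate and butyrate in ruminal fluid. Provides seven
    candidate model forms (one stoichiometric, six empirical), a three-level
    linear mixed-effects meta-analysis (random intercepts for experiment,
    treatment within experiment, and cow), leave-one-experiment-out
    cross-validation with RMSEP, Lin's concordance correlation and a
    decomposition of the mean squared error of prediction, a registry of
    published calibrated coefficients, and a hierarchical synthetic-data
    generator that emulates the statistical structure of multi-experiment
    rumen-fermentation studies.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
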
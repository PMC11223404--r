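Package: wcstsim
Title: Cycle-Budgeted Executive-Function Simulation of the Wisconsin Card Sorting Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the 128-card Wisconsin Card Sorting Task (WCST) with a
    cycle-limited cognitive agent whose updating, shifting, and inhibition
    processes are parameterised at discrete ability levels. Runs factorial
    grids of executive-function variants crossed with deliberation cycle
    budgets over cohorts of virtual participants, scores perseveration errors,
    non-perseveration errors, categories obtained, and correct sorts under
    Heaton-style administration rules, analyses the resulting tables
    (descriptives, one-way ANOVA with eta squared, ANCOVA with covariate
    adjustment, Bonferroni pairwise comparisons with Cohen's d), and
    classifies per-model mean perseveration errors against standard-error
    boundary intervals derived from cancer-survivor comparison groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
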
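Package: forestNCP
Title: Multi-Objective Forest Restoration Prioritization with Equity Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systematic conservation planning tools for budget-constrained
    forest restoration prioritization across Nature's Contributions to
    People (NCP): climate change mitigation (30-year carbon accumulation),
    biodiversity value (species Area-of-Habitat restoration targets), and
    societal reliance on forests for livelihoods, energy, and housing
    material. Provides a reproducible synthetic-landscape generator,
    NCP feature assembly with an IUCN-inspired habitat target-setting
    protocol, a minimum weighted proportional-shortfall linear programming
    core solved with HiGHS, four plan schemes swept over budget increments
    to produce NCP accumulation curves, selection-frequency maps and
    cessation budgets, and distributional-equity reports comparing the
    beneficiaries of each plan with population-weighted national averages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.9) with numpy and scipy (>= 1.9) on the
    PATH as 'python' (used for the HiGHS linear-programming backend)
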
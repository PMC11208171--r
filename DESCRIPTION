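Package: acetoflux
Title: Stoichiometric Electron-Flow and Bioenergetic Modelling of Acetogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact-arithmetic stoichiometric modelling of the Wood-Ljungdahl
    pathway and its chemiosmotic energy conservation in the acetogen
    Acetobacterium woodii. Assembles the electron-carrier flow network
    (ferredoxin, NAD(H), hydrogen) active under a given genotype (wild type or
    hydrogenase-free mutant) and cultivation condition (CO, formate, H2 + CO2,
    fructose; sodium depletion; bicarbonate uncoupling), solves the unique
    steady-state flux distribution per unit product with exact rational
    arithmetic, and accounts the sodium-ion ledger of the Rnf complex and the
    Na+ F1F0 ATP synthase to give net ATP yields per acetate. Includes a
    registry of named genotype-by-condition scenarios, a quantitative analysis
    layer for batch and resting-cell experiments (endpoint substrate:product
    ratios, activity fold changes, exponential growth-rate fitting, specific
    conversion rates, SNP population-frequency reporting), and seeded
    generators of synthetic growth curves, stoichiometry-consistent metabolite
    timecourses and SNP tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
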
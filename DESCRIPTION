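Package: campusfp
Title: Integrated Campus Environmental Footprint Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes greenhouse-gas, reactive-nitrogen, phosphorus and
    water footprints for an institutional campus from a single shared
    activity ledger and per-footprint emission-factor tables; projects
    business-as-usual growth with population, floor-area and food-demand
    drivers; applies and composes sustainability-action-plan strategies
    (fuel switches, efficiency measures, food substitutions, renewable
    offsets) as declarative ledger transformations; and converts GHG and
    nitrogen releases into monetary damage costs by pollutant form,
    release medium and impact sector, including social-cost-of-carbon
    valuation and NOx health-cost savings. Ships a seeded synthetic
    campus generator so the whole pipeline is testable without
    institutional data, and a command-line interface for batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
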
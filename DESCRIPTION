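Package: forcarbuq
Title: Monte Carlo Uncertainty Quantification for Regional Forest Carbon Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates regional forest net biome exchange (NBE) and ecosystem
    carbon stock under combined climate (RCP x GCM) and harvest-intensity
    scenarios, propagating every sampled source of uncertainty (initial stand
    age and site fertility, soil spin-up state, model parameter pools, crown
    height, drained organic-soil emission coefficients, peat carbon stock,
    climate-model choice and harvest-target noise) through an annual surrogate
    stand and soil carbon model by Monte Carlo. Provides greenhouse-gas
    accounting in CO2 equivalents, canonical-correlation redundancy-index
    attribution of output variance to uncertainty sources, and empirical-CDF
    risk curves for carbon-sink targets. Ships a seeded synthetic landscape
    generator emulating segmented national forest-inventory data so the whole
    pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
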
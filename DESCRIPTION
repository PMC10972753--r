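Package: heatfootprint
Title: Heat-Stress Disaster Footprints Across Global Supply Chains
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated climate-epidemiology-economy pipeline for
    quantifying the economic footprint of heat stress. Gridded daily
    temperature and humidity are converted to wet bulb globe temperature
    (WBGT) heat-stress exposure; heatwaves are detected under static and
    dynamic percentile thresholds and translated into excess mortality via
    climate-zone relative risks, then monetized with value-of-statistical-life
    methods; WBGT exposure-response functions yield daily labour-capacity
    losses by work-intensity class, which are propagated through a
    multiregional supply-chain network with an adaptive input-output
    simulator (constrained Leontief production, proportional rationing,
    inventory and order dynamics) to decompose total value-added losses
    into direct and supply-chain-propagated components. A synthetic-data
    module generates climate grids, population fields and balanced
    multiregional input-output tables so the full pipeline runs and is
    tested without licensed or large external inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    pracma,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epidemiology, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ario.R'
    'calendar.R'
    'generate-climate.R'
    'generate-mrio.R'
    'generate-population.R'
    'health.R'
    'heatwave.R'
    'io.R'
    'labour.R'
    'pipeline.R'
    'wbgt.R'
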
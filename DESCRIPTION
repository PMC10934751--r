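Package: espartoflux
Title: Transpiration of Esparto Grass Under Pine Competition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for leaf-level transpiration of esparto grass
    (Macrochloa tenacissima) growing under contrasting levels of Aleppo pine
    competition in a semi-arid Mediterranean climate. Converts raw gas-exchange
    chamber records into transpiration rates (mm/h), computes a neighbourhood
    competition index from pine perimeters and distances, screens seasonal
    Spearman correlations between transpiration and soil/environmental
    covariates, and fits a combined exponential power model of transpiration
    versus soil water content with site dummy effects via log-linearisation,
    backward stepwise selection and DFFITS influential-point removal. A
    synthetic-study generator reproduces the factorial sampling design and
    seasonal microclimate so the whole pipeline runs and is testable without
    field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
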
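Package: phenotab
Title: ISA-Tab Phenotyping Configurations and MIAPPE Compliance for Plant
    Phenotyping Metadata
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reads, writes, scaffolds, validates and summarises plant
    phenotyping datasets formatted as ISA-Tab (Investigation/Study/Assay)
    archives. Implements the MIAPPE (Minimum Information About a Plant
    Phenotyping Experiment) checklist as an executable compliance model, the
    Phenotyping Configuration study schemas (Basic, Field, Greenhouse) and
    Phenotyping Assay schema with additive schema extension, Trait Definition
    Files linked to sample-by-variable observation matrices, cross-study
    aggregation of observations, and a deterministic generator of synthetic
    MIAPPE-compliant datasets for testing pipelines without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
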
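Package: ImmunoCube
Title: Star-Schema Warehouse and OLAP Cube for Heterogeneous Immunoassay Results
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: A self-contained dimensional warehouse for systems-immunology
    assay results (multiplex bead immunoassays, electrochemiluminescence
    panels, phosphoepitope flow cytometry) with user-driven ingestion and
    linkage workflows and a ROLAP cube for interactive aggregation,
    segregation and drill-through. Batch result sheets and flexible-format
    metadata sheets are loaded into a star schema (aliquot-level fact table
    joined to person, sample, analyte and source dimensions), incoming
    metadata values are harmonized against controlled vocabularies, and
    laboratory aliquot identifiers are reconciled to samples and persons by
    recorded string transforms. A synthetic influenza-vaccination cohort
    generator with planted, parameterized effects makes the full pipeline
    testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    DBI,
    RSQLite,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'warehouse.R'
    'batch_ingest.R'
    'metadata_ingest.R'
    'id_linkage.R'
    'cube.R'
    'synthetic_study.R'
    'pipeline.R'
    'cli.R'
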
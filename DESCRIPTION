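Package: dwcdq
Title: Fitness-for-Use Data Quality Assessment for Darwin Core Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative data-quality engine for biodiversity occurrence
    records. Users describe their quality needs as a profile (a use case,
    the information elements that matter for it, and measurement, validation
    and enhancement policies); the engine evaluates Darwin Core occurrence
    records and datasets with a catalogue of mechanisms (completeness,
    coordinate conformity, point-radius country consistency, taxon-hierarchy
    backfill, gazetteer lookup, scientific-name suggestion) and emits a
    quality-status report of measures, validations and proposed amendments.
    Reports support both quality assurance (filtering a dataset to its
    fit-for-use subset) and quality control (applying accepted amendment
    proposals). Includes a deterministic synthetic occurrence-data generator
    with injected defect rates and ground-truth labels, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
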
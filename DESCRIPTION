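Package: raschval
Title: Structural Validity of Polytomous Scales via the Partial Credit Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rasch measurement analysis of polytomous patient-reported
    outcome scales using the partial credit model. Provides marginal
    maximum likelihood item calibration, weighted likelihood person
    estimation, item and person fit residuals, item-trait interaction
    chi-square tests across ability class intervals, disordered-threshold
    detection, residual-correlation screening for local item dependence,
    testlet (super-item) accommodation, differential item functioning by
    two-way analysis of variance on residuals, the principal-component
    t-test of unidimensionality, the Person Separation Index, and
    ordinal-to-interval score conversion tables. Includes a synthetic
    response generator with planted local dependence, differential item
    functioning and misfit for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    pracma,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'scale-data.R'
    'pcm-core.R'
    'estimate-items.R'
    'estimate-persons.R'
    'fit-diagnostics.R'
    'residual-structure.R'
    'interval-scoring.R'
    'synthetic-data.R'
    'pipeline.R'
    'report-io.R'
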
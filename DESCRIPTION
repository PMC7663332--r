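Package: corrqsar
Title: QSAR Modelling Pipeline for F508del-CFTR Corrector Potency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for quantitative structure-activity
    relationship (QSAR) modelling of F508del-CFTR corrector potency.
    Implements the six charge- and energy-based molecular descriptors
    retained in the published corrector models (nonbonded and angle-bend
    potential energies, negatively charged accessible surface area,
    charge-weighted accessible surface areas and polar van der Waals
    surface area), Kennard-Stone train/test design on the
    response-augmented descriptor matrix, contingency-based descriptor
    pruning, iterative partial least squares regression with
    relative-importance elimination and leave-one-out validation, the
    external predictivity statistic r2pred, and the two published linear
    scoring equations.  Ships the 80-compound corrector roster with the
    printed potency and descriptor values, and a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
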
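Package: cahcea
Title: Cost-Effectiveness Analysis of Newborn Screening for Congenital
    Adrenal Hyperplasia
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-tree cost-effectiveness model comparing newborn
    screening for classical congenital adrenal hyperplasia (CAH) against
    clinical diagnosis, from the perspective of the Brazilian public health
    system.  Implements the screening false-positive cascade, salt-wasting
    hospitalization and simple-virilizing long-term therapy cost ledgers,
    incremental cost-effectiveness ratios per discounted life-year saved,
    deterministic one-way sensitivity analysis with tornado ordering,
    cohort-derived parameter estimators, and a synthetic patient-cohort
    generator so every estimation stage is testable without patient records.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
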
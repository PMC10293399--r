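Package: hipfi
Title: Deficit-Accumulation Frailty Index for Hip-Fracture Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a 21-item deficit-accumulation frailty index (FI) from
    coded hip-fracture admission records: 15 dichotomous comorbidities mapped
    from ICD-10-AM diagnosis codes via a configurable prefix map, previous
    fragility fracture, pre-admission pressure ulcer, three New Mobility Score
    items recoded to ordinal fractions, and nursing-home provenance. Scores
    each admission as the proportion of deficits present, stratifies the
    cohort into low/medium/high risk tertiles, fits tertile-adjusted logistic
    regressions for adverse inpatient outcomes (delirium, prolonged length of
    stay, inpatient mortality, new nursing-home admission), and compares
    nested risk models by area under the ROC curve. Includes a seeded
    synthetic-cohort generator emulating national hip-fracture audit data so
    the whole pipeline is testable without registry access.
License: MIT + file LICENSE
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
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
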
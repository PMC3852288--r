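Package: owascreen
Title: Open-World Pre-Screening of Clinical Trial Eligibility with
    Partially Known Patient Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Determines clinical-trial eligibility from incomplete patient
    records under the open world assumption. Eligibility criteria are
    evaluated in three-valued (strong Kleene) logic so that patients are
    classified as eligible, not eligible (with the causing criteria), or
    potentially eligible with the exact missing criteria identified, instead
    of being over-rejected by negation-as-failure. Includes a closed-world
    baseline for comparison, a declarative rule language binding raw patient
    field tables to criterion statuses, a compiler emitting an OWL 2 ontology
    design pattern (one class per criterion plus its complement, and per-trial
    include/exclude defined classes) with a built-in instance classifier for
    that Boolean fragment used to cross-check the engine, a synthetic-cohort
    generator with controlled missingness, and missingness and screening
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
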
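Package: rxswitch
Title: Rule-Based Switching of Medications to a Hospital Drug Formulary
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clinical decision support for medication reconciliation at
    hospital admission. Implements a five-step matching algorithm that
    translates a patient's pre-admission prescriptions into products of a
    hospital drug formulary (HDF): identity match, pharmaceutical
    equivalents (same active moiety, strength, and application form),
    pharmaceutical alternatives (same moiety, different strength, with
    dose-regimen recomputation), therapeutic equivalents (different moiety
    within an ATC-scoped interchange class, with conversion-factor dose
    adjustment), and a residual manual-handling category. Includes
    combination-product splitting, a curatable therapeutic-interchange
    knowledge base with equipotent daily doses and exclusion rules, a
    deterministic synthetic-data generator with ground-truth manifests,
    and performance accounting for evaluation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
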
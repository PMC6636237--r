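Package: scanassist
Title: Ontology-Based Scan Assistance and Evaluation for Early Pregnancy Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A knowledge-engineering toolkit for intelligent scan assistance in
    early pregnancy transvaginal ultrasound. Provides a triple-store model of
    ultrasound semiology (signs, disorders, echographic views) with a minimal
    Turtle serialization, the graph-reasoning algorithm that derives a
    personalized imaging protocol and a ranked differential from identified
    signs, a scan-session workflow with structured reporting, the 15-item
    image-set quality score and 5-level report trust scale, the statistical
    battery for paired crossover evaluation studies (paired t tests, exact
    McNemar tests, Cohen weighted kappa, proportion differences), and a seeded
    stochastic simulator of a two-operator, 32-case, two-mode diagnostic
    accuracy study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
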
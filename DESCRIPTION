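Package: econsultcost
Title: Cost Modelling and Usage Analytics for Digital Consultation
    Services in Primary Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Activity-based cost model for web-based triage and
    consultation ("eConsult") services in general practice.  Composes
    per-category administrative and GP processing times from task-level
    timing estimates, weights them by the category mix of submissions,
    converts the expected times into per-submission cost savings against
    conventional appointments, and computes the annual submission rate
    per registered patient needed to break even against a per-patient
    licence charge.  Includes a scenario engine for directed-marketing
    category mixes, usage analytics for triage-site event logs
    (conversion rates, annualised submission rates, demographic shares,
    deprivation association, survey proportions), and a seeded synthetic
    event-log generator for testing the analytics without access to
    pilot log data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
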
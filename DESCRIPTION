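Package: ppmsanon
Title: Privacy-Preserving Anonymization of Periodically Released
    Spontaneous Reporting Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for anonymizing quarterly releases of spontaneous
    reporting system (SRS) adverse drug event data under the
    PPMS(k, theta*)-bounding privacy model.  Follow-up reports share a
    CaseID across releases, which lets an adversary link a target's
    quasi-identifier to one release and then exclude candidate cases by
    inspecting earlier releases (B-attack), later releases (F-attack),
    or first-appearance knowledge (L-attack).  The package implements
    the PPMS, PPMS+ and PPMS++ anonymization algorithms (new-case
    bounding plus QID-covering), a single-release MS-style baseline, a
    BFL-attack auditor, anonymization-quality metrics (normalized
    information loss, dangerous identity ratio, dangerous sensitivity
    ratio), proportional-reporting-ratio (PRR) signal utility
    evaluation, and a seeded synthetic SRS series generator with
    follow-up CaseIDs, skewed symptom frequencies and planted
    demographic adverse-reaction rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
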
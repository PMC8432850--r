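Package: icd2iss
Title: Automated Injury Severity Scores from ICD-10-GM Diagnosis Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms German-modification ICD-10 (ICD-10-GM) trauma
    diagnosis codes into the US clinical-modification (ICD-10-CM) eight-character
    format via pluggable recode and seventh-character policy tables, maps the
    resulting codes to Abbreviated Injury Scale (AIS) severities and ISS body
    regions through a GEM-style longest-prefix lookup with GEMmin/GEMmax
    disambiguation, computes the Injury Severity Score (ISS), and validates
    automatic against manual scoring with paired TOST equivalence testing,
    Wilcoxon signed-rank tests, linearly weighted Cohen's kappa, ISS-group
    cross-tabulation and TOST-based sample-size calculation. Ships fixture
    tables and a synthetic trauma-cohort generator so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
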
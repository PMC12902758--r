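Package: polyrx
Title: Polypharmacy Characterization from OMOP-Shaped Inpatient Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds merged inpatient admission episodes with post-discharge
    follow-up from OMOP-CDM-shaped tables, maps drug codes to WHO ATC codes
    via a product dictionary or the CDM vocabulary, computes each patient's
    maximum daily concomitant drug-ingredient count, assigns a four-level
    polypharmacy category, and mines single and combination ATC second-level
    prescribing patterns stratified by age. Includes a synthetic cohort
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.12),
    jsonlite,
    pracma,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
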
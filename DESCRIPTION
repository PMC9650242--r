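Package: sepsis3icu
Title: Sepsis-3 Phenotyping on ICU Event Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Operationalises the Sepsis-3 clinical criteria on long-format
    intensive-care event tables (admissions, drug administrations, numeric
    measurements, list observations) shaped like the AmsterdamUMCdb CSV
    exports. Computes daily SOFA organ-dysfunction scores over configurable
    24-hour windows relative to admission, detects suspected infection via
    antibiotic escalation (rise in the maximum antibiotic rank, or in the
    number of agents at that rank, with at least one intravenous agent),
    applies prophylaxis rules (selective digestive decontamination,
    perioperative antibiotics after elective surgery), and flags per-window
    sepsis episodes and septic shock. Includes a baseline comparison against
    admission-time sepsis criteria and a synthetic cohort generator with
    planted ground truth so the full pipeline is testable without access to
    restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
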
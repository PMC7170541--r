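Package: apmonitor
Title: Census-Based Monitoring of Antipsychotic Prescribing in Dementia
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for 'real time' surveillance of antipsychotic
    prescribing in a dementia caseload from electronic health records (EHR):
    seeded synthetic mental-health EHR generation with ground truth,
    deterministic lexicon-based extraction of diagnosis assertions and
    medication references (with start/stop and negation context) from
    free-text notes, census-date cohort ascertainment of patients with
    dementia and recent antipsychotic use (a baseline algorithm and a refined
    variant that drops single-reference patients and stopped medications,
    plus sensitivity exclusions for comorbid psychosis and superseding
    diagnoses), monitoring-form completion linkage with a reverse check for
    algorithm false negatives, and team-level monthly feedback reports with
    trend series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
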
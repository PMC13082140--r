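Package: nsrbias
Title: Clinician Bias Exposure in Psychiatric Notes via the Negative
    Sentence Ratio
Version: 0.1.0
Authors@R:
    person("nsrbias", "maintainers", email = "nsrbias@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify patient exposure to clinician bias in
    emergency-department psychiatric notes.  Notes are sectionized
    (Chief Complaint, History of Present Illness, Mental Status Exam,
    Collateral), split into sentences, filtered for clinical relevance,
    and sentiment-labeled through a pluggable backend whose raw outputs
    are parsed through a five-subtype taxonomy of unlabelable responses
    with rule-based recovery and a strict-prompt rerun.  The per-patient
    Negative Sentence Ratio (NSR) summarizes the labels and enters
    interaction logistic regressions linking bias exposure to
    schizophrenia-spectrum diagnosis.  A synthetic-data module generates
    cohorts and notes with known ground truth so the whole pipeline is
    testable without access to protected health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
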
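#' Run the full note-to-NSR pipeline
#'
#' Section extraction, sentence splitting, relevance filtering, note
#' filters, backend labeling with NA-subtype resolution, and per-patient
#' NSR summaries — the complete path from raw note text to the bias
#' metric.  Patients whose notes fail the word-count or sentence-count
#' filters are excluded from the summaries.
#'
#' @param notes data frame with `patient_id` and `text`.
#' @param backend labeling backend (default: the deterministic lexicon
#'   backend).
#' @param config an `nsr_labeler_config`.
#' @return list with `sentences` (all extracted sentences with relevance
#'   flags), `note_filters` (per-note keep/drop decisions), `labels`
#'   (resolved labels for kept sentences of kept notes), `removed`
#'   (E_TEXT sentences), `dispositions`, and `summaries` (per-patient
#'   counts and NSR).
#' @export
run_pipeline <- function(notes, backend = lexicon_backend,
                         config = labeler_config()) {
  prep <- preprocess_notes(notes)
  kept_patients <- prep$notes$patient_id[prep$notes$keep]
  corpus <- prep$sentences[prep$sentences$relevant &
                             prep$sentences$patient_id %in% kept_patients, ,
                           drop = FALSE]
  lab <- label_sentences(corpus, backend, config)
  list(
    sentences = prep$sentences,
    note_filters = prep$notes,
    labels = lab$labels,
    removed = lab$removed,
    dispositions = lab$dispositions,
    summaries = summarize_patients(lab$labels)
  )
}

#' Generating coefficients as fitted-model term labels
#'
#' Expands a scenario outcome's semantic coefficient list into the term
#' labels a fitted logistic model produces (treatment coding, White and
#' Female references), for parameter-recovery checks via [coef_lookup()].
#'
#' @param truth `truth` element returned by [generate_cohort()].
#' @param outcome outcome name (e.g. `"SCZ"`).
#' @return data frame with `term` and `value` (log-odds scale), including
#'   the resolved intercept.
#' @export
truth_coefficients <- function(truth, outcome) {
  cc <- truth$coeffs[[outcome]]
  if (is.null(cc)) stop("no generating coefficients for outcome ", outcome)
  rl <- function(prefix, v, suffix = "") {
    data.frame(term = paste0(prefix, names(v), suffix), value = unname(v),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    data.frame(term = "(Intercept)", value = cc$intercept),
    data.frame(term = "age", value = cc$age),
    data.frame(term = "sexMale", value = cc$male),
    rl("race_ethnicity", cc$race),
    data.frame(term = "ses_z", value = cc$ses),
    data.frame(term = "trauma_history", value = cc$trauma),
    data.frame(term = "substance_history", value = cc$substance),
    data.frame(term = "trauma_history:substance_history",
               value = cc$trauma_substance),
    rl("sexMale:race_ethnicity", cc$race_male),
    rl("race_ethnicity", cc$race_ses, ":ses_z"),
    data.frame(term = "sexMale:ses_z", value = cc$male_ses),
    rl("sexMale:race_ethnicity", cc$race_male_ses, ":ses_z"),
    data.frame(term = "nsr", value = cc$nsr),
    rl("race_ethnicity", cc$nsr_race, ":nsr"),
    data.frame(term = "sexMale:nsr", value = cc$nsr_male),
    data.frame(term = "ses_z:nsr", value = cc$nsr_ses)
  )
  rownames(out) <- NULL
  out
}
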
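## Negative Sentence Ratio: the per-patient bias-exposure metric.
##
## n_sentences = n_NA + n_negative + n_neutral + n_positive
## NSR         = n_negative / n_sentences
##
## Retained NA labels count in the denominator; E_TEXT sentences were
## removed upstream and never reach this module.

#' Summarize one patient's resolved sentence labels
#'
#' @param labels character vector of final labels (`"negative"`,
#'   `"neutral"`, `"positive"`, or `NA` for retained NA).
#' @return object of class `nsr_summary`: one-row data frame with the four
#'   counts, `n_sentences` and `nsr`.
#' @export
summarize_patient <- function(labels) {
  if (length(labels) == 0)
    stop("NSR undefined for a patient with zero sentences; ",
         "the patient should have been dropped by the note filters")
  out <- data.frame(
    n_na = sum(is.na(labels)),
    n_negative = sum(labels == "negative", na.rm = TRUE),
    n_neutral = sum(labels == "neutral", na.rm = TRUE),
    n_positive = sum(labels == "positive", na.rm = TRUE)
  )
  out$n_sentences <- out$n_na + out$n_negative + out$n_neutral +
    out$n_positive
  stopifnot(out$n_sentences == length(labels))
  out$nsr <- out$n_negative / out$n_sentences
  class(out) <- c("nsr_summary", class(out))
  out
}

#' Summarize all patients in a labeled sentence table
#'
#' @param labeled data frame with `patient_id` and `label` (as produced by
#'   [label_sentences()]).
#' @return data frame, one row per patient, with the count columns and
#'   `nsr`.
#' @export
summarize_patients <- function(labeled) {
  stopifnot(all(c("patient_id", "label") %in% names(labeled)))
  dt <- data.table::as.data.table(labeled)
  out <- dt[, .(
    n_na = sum(is.na(label)),
    n_negative = sum(label == "negative", na.rm = TRUE),
    n_neutral = sum(label == "neutral", na.rm = TRUE),
    n_positive = sum(label == "positive", na.rm = TRUE)
  ), by = patient_id]
  out[, n_sentences := n_na + n_negative + n_neutral + n_positive]
  out[, nsr := n_negative / n_sentences]
  as.data.frame(out)
}

#' Per-group NSR summary table
#'
#' Group means and standard deviations of the NSR, negative-sentence
#' counts, total sentence counts and NA counts, in the shape of a cohort
#' characteristics table.
#'
#' @param summaries per-patient summaries from [summarize_patients()].
#' @param cohort cohort data frame with `patient_id` and the grouping
#'   column.
#' @param group name of the grouping column in `cohort`.
#' @return data frame with one row per group.
#' @export
cohort_nsr_table <- function(summaries, cohort, group = "cohort_group") {
  stopifnot(group %in% names(cohort))
  df <- merge(summaries, cohort[c("patient_id", group)], by = "patient_id")
  grp_values <- unique(cohort[[group]])
  empty <- setdiff(grp_values, unique(df[[group]]))
  if (length(empty))
    warning("groups with no summarized patients omitted: ",
            paste(empty, collapse = ", "))
  dt <- data.table::as.data.table(df)
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  out <- dt[, .(
    n = .N,
    nsr_mean = mean(nsr), nsr_sd = sd0(nsr),
    negative_mean = mean(n_negative), negative_sd = sd0(n_negative),
    sentences_mean = mean(n_sentences), sentences_sd = sd0(n_sentences),
    na_mean = mean(n_na), na_sd = sd0(n_na)
  ), by = group]
  as.data.frame(out[order(get(group))])
}
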
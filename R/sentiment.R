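## Sentiment labeling: pluggable backend, robust parsing of raw labeler
## output through a five-subtype taxonomy of unlabelable responses,
## rule-based recovery, a single strict-prompt rerun, and validation
## metrics.

SENTIMENT_CLASSES <- c("negative", "neutral", "positive")

#' Labeler configuration
#'
#' Backend contract: a backend is a function
#' `function(sentences, prompt, config)` returning one raw output string
#' for the batch, expected (but not trusted) to be a JSON map from 0-based
#' sentence index to a label.  Defaults mirror a reproducible LLM setup
#' (temperature 0.001, seed 42).
#'
#' @param backend_id identifier of the backend.
#' @param temperature sampling temperature (>= 0).
#' @param seed backend seed.
#' @param batch_size maximal sentences per prompt (`NA` = one note per
#'   batch).
#' @return object of class `nsr_labeler_config`.
#' @export
labeler_config <- function(backend_id = "lexicon", temperature = 0.001,
                           seed = 42L, batch_size = NA_integer_) {
  stopifnot(temperature >= 0)
  structure(list(backend_id = backend_id, temperature = temperature,
                 seed = as.integer(seed), batch_size = batch_size),
            class = "nsr_labeler_config")
}

#' Labeling prompts
#'
#' The first-pass prompt asks the model to read the note from the patient's
#' perspective.  The strict rerun variant (packaged wording, used after an
#' unusable first answer) demands exactly one label per sentence in strict
#' JSON.
#'
#' @param config an `nsr_labeler_config` (reserved for backend-specific
#'   prompt variants; unused by the packaged prompts).
#' @param variant `"first_pass"` or `"strict"`.
#' @return prompt instruction string.
#' @export
build_prompt <- function(config = labeler_config(),
                         variant = c("first_pass", "strict")) {
  variant <- match.arg(variant)
  if (variant == "first_pass") {
    paste0(
      "As a patient at a medical center, medical doctors write lots of ",
      "clinical notes about you. Your task is to analyze the sentiment of ",
      "a series of sentences your doctor wrote about you. For each ",
      "sentence, how do you feel reading this description of you? Please ",
      "assign a sentiment score of negative, neutral, or positive for ",
      "each sentence.")
  } else {
    paste0(
      "Your previous answer could not be used. Label each sentence again ",
      "and return ONLY a JSON object mapping each sentence index to ",
      "exactly one sentiment label, for example {\"0\":\"neutral\"}. Each ",
      "value must be exactly one of \"negative\", \"neutral\", or ",
      "\"positive\". Return one label per sentence and no other text.")
  }
}

#' Assemble the full prompt for a sentence batch
#'
#' @param sentences non-empty character vector.
#' @inheritParams build_prompt
#' @return prompt string with the numbered sentences appended.
#' @export
format_prompt <- function(sentences, config = labeler_config(),
                          variant = "first_pass") {
  if (length(sentences) == 0)
    stop("cannot build a prompt for an empty sentence batch")
  paste0(build_prompt(config, variant), "\n\n",
         paste(sprintf("%d: %s", seq_along(sentences) - 1L, sentences),
               collapse = "\n"))
}

#' Classify sentences with the packaged sentiment cue lexicon
#'
#' @param text character vector.
#' @return character vector of labels (negative cues dominate, then
#'   positive; cue-free sentences are neutral).
#' @export
lexicon_classify <- function(text) {
  lex <- sentiment_lexicon()
  rx <- function(cues) paste0("(?i)\\b(", paste(cues, collapse = "|"), ")\\b")
  neg <- grepl(rx(lex$negative), text, perl = TRUE)
  pos <- grepl(rx(lex$positive), text, perl = TRUE)
  ifelse(neg, "negative", ifelse(pos, "positive", "neutral"))
}

#' Deterministic lexicon labeling backend
#'
#' Stand-in for an LLM backend: returns a well-formed JSON label map keyed
#' on the planted lexicon cues, exact on synthetic sentences.
#'
#' @param sentences character vector (one batch).
#' @param prompt ignored (kept for the backend contract).
#' @param config ignored (kept for the backend contract).
#' @return one raw output string (a JSON label map).
#' @export
lexicon_backend <- function(sentences, prompt = NULL, config = NULL) {
  labs <- lexicon_classify(sentences)
  paste0("{", paste(sprintf('"%d":"%s"', seq_along(labs) - 1L, labs),
                    collapse = ","), "}")
}

## --- parsing ---------------------------------------------------------------

.distinct_sentiments <- function(x) {
  m <- gregexpr("(?i)\\b(negative|neutral|positive)\\b", x, perl = TRUE)[[1]]
  if (m[1] == -1L) character(0)
  else unique(tolower(regmatches(x, list(m))[[1]]))
}

.classify_refusal <- function(x) {
  low <- tolower(x)
  if (grepl("cannot|can not|will not|won['’]t|not able to comply", low))
    "REFUSE"
  else if (grepl("unable|incomplete|irrelevant|uninterpretable", low))
    "E_TEXT"
  else "ERROR"
}

## Ordered subtype rules for one JSON value (first match wins):
## clean label; hyphen/slash-joined or multiple sentiment words ->
## TWO_LABELS; one sentiment word plus extra text -> EXTRACT; refusal
## phrases -> REFUSE; inability phrases -> E_TEXT; anything else -> ERROR.
.classify_value <- function(v) {
  v <- paste(as.character(unlist(v)), collapse = " ")
  norm <- tolower(trimws(gsub("[.!]+$", "", trimws(v))))
  if (norm %in% SENTIMENT_CLASSES)
    return(list(value = norm, subtype = "none"))
  found <- .distinct_sentiments(v)
  if (length(found) >= 2 ||
      grepl("(?i)\\b(negative|neutral|positive)\\s*[-/]\\s*(negative|neutral|positive)\\b",
            v, perl = TRUE))
    return(list(value = NA_character_, subtype = "TWO_LABELS"))
  if (length(found) == 1)
    return(list(value = NA_character_, subtype = "EXTRACT"))
  list(value = NA_character_, subtype = .classify_refusal(v))
}

#' Parse one raw labeler output for a sentence batch
#'
#' Total: every raw string yields, per sentence, either one of the three
#' sentiment labels or exactly one NA subtype.  Valid JSON label maps are
#' read per index; indices missing from the map, and raw strings that are
#' not JSON objects at all, are classified through the refusal/inability
#' rules (REFUSE, E_TEXT) and default to ERROR.
#'
#' @param raw raw output string for the batch.
#' @param batch_size number of sentences in the batch.
#' @return data frame with one row per sentence: `index` (0-based),
#'   `value` (label or `NA`), `na_subtype` (`"none"` when labeled),
#'   `provenance` (`"first_pass"`), and `raw_value` (the JSON value string
#'   where one existed, for EXTRACT recovery).
#' @export
parse_output <- function(raw, batch_size) {
  stopifnot(length(raw) == 1L, batch_size >= 1L)
  ## parse_json never interprets the string as a file path or URL
  parsed <- tryCatch(jsonlite::parse_json(raw, simplifyVector = FALSE),
                     error = function(e) NULL)
  is_map <- is.list(parsed) && !is.null(names(parsed))
  idx <- seq_len(batch_size) - 1L
  value <- rep(NA_character_, batch_size)
  subtype <- rep(NA_character_, batch_size)
  raw_value <- rep(NA_character_, batch_size)
  if (is_map) {
    for (i in idx) {
      v <- parsed[[as.character(i)]]
      if (is.null(v)) {
        subtype[i + 1L] <- .classify_refusal(raw)
      } else {
        cl <- .classify_value(v)
        value[i + 1L] <- cl$value
        subtype[i + 1L] <- cl$subtype
        raw_value[i + 1L] <- paste(as.character(unlist(v)), collapse = " ")
      }
    }
  } else {
    subtype[] <- .classify_refusal(raw)
  }
  data.frame(index = idx, value = value, na_subtype = subtype,
             provenance = "first_pass", raw_value = raw_value,
             stringsAsFactors = FALSE)
}

#' Rule-based recovery for EXTRACT-subtype outputs
#'
#' Searches the raw JSON value case-insensitively for the three sentiment
#' strings.  Exactly one distinct match recovers that label; two or more
#' reclassify the output as TWO_LABELS; zero leaves it NA.
#'
#' @param raw_value the JSON value string of an EXTRACT output.
#' @return list with `value` (label or `NA`) and `subtype`.
#' @export
recover_extract <- function(raw_value) {
  found <- .distinct_sentiments(raw_value)
  if (length(found) == 1) list(value = found, subtype = "none")
  else if (length(found) >= 2) list(value = NA_character_,
                                    subtype = "TWO_LABELS")
  else list(value = NA_character_, subtype = "EXTRACT")
}

#' Resolve first-pass labels: recovery, strict rerun, E_TEXT removal
#'
#' EXTRACT outputs go through [recover_extract()]; TWO_LABELS, ERROR and
#' REFUSE sentences are rerun exactly once through the backend with the
#' strict prompt and re-parsed; sentences still NA after these steps are
#' retained as NA (they count toward the NSR denominator); E_TEXT sentences
#' are removed from the corpus.  Disposition counts are conserved:
#' labeled + retained NA + removed equals the input count.
#'
#' @param parsed data frame from [parse_output()].
#' @param sentences character vector of the batch's sentence texts.
#' @param backend labeling backend (see [labeler_config()] for the
#'   contract).
#' @param config an `nsr_labeler_config`.
#' @return list with `labels` (retained rows, including retained NA),
#'   `removed` (E_TEXT rows) and `dispositions` (named counts).
#' @export
resolve_labels <- function(parsed, sentences, backend = lexicon_backend,
                           config = labeler_config()) {
  stopifnot(nrow(parsed) == length(sentences))
  first_subtype <- parsed$na_subtype

  ex <- which(first_subtype == "EXTRACT")
  for (i in ex) {
    rec <- recover_extract(parsed$raw_value[i])
    if (!is.na(rec$value)) {
      parsed$value[i] <- rec$value
      parsed$provenance[i] <- "extract_recovery"
    }
  }

  rerun <- which(first_subtype %in% c("TWO_LABELS", "ERROR", "REFUSE"))
  if (length(rerun)) {
    reparsed <- tryCatch({
      raw2 <- backend(sentences[rerun],
                      prompt = format_prompt(sentences[rerun], config,
                                             "strict"),
                      config = config)
      parse_output(raw2, length(rerun))
    }, error = function(e) {
      warning("backend failure on rerun; sentences retained as NA/ERROR: ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(reparsed)) {
      ok <- !is.na(reparsed$value)
      parsed$value[rerun[ok]] <- reparsed$value[ok]
      parsed$provenance[rerun[ok]] <- "rerun"
    }
  }
  parsed$provenance[is.na(parsed$value) & first_subtype != "none"] <-
    "unresolved"

  etext <- first_subtype == "E_TEXT" & is.na(parsed$value)
  labels <- parsed[!etext, , drop = FALSE]
  removed <- parsed[etext, , drop = FALSE]
  disp <- c(
    input = nrow(parsed),
    labeled_first_pass = sum(first_subtype == "none"),
    extract_recovered = sum(labels$provenance == "extract_recovery"),
    rerun_resolved = sum(labels$provenance == "rerun"),
    retained_na = sum(is.na(labels$value)),
    removed_e_text = nrow(removed)
  )
  stopifnot(disp[["labeled_first_pass"]] + disp[["extract_recovered"]] +
              disp[["rerun_resolved"]] + disp[["retained_na"]] +
              disp[["removed_e_text"]] == disp[["input"]])
  list(labels = labels, removed = removed, dispositions = disp)
}

#' Label a sentence corpus through a backend, batch by note
#'
#' Convenience driver: batches the kept sentences of each patient's note,
#' calls the backend, parses and resolves the labels.
#'
#' @param sentences data frame with `patient_id` and `text` (typically the
#'   relevant sentences from [preprocess_notes()]).
#' @inheritParams resolve_labels
#' @return list with `labels` (input rows plus `label`, `na_subtype`,
#'   `provenance`), `removed` (E_TEXT rows) and `dispositions`.
#' @export
label_sentences <- function(sentences, backend = lexicon_backend,
                            config = labeler_config()) {
  stopifnot(all(c("patient_id", "text") %in% names(sentences)))
  pieces <- split(seq_len(nrow(sentences)), sentences$patient_id)
  lab_list <- vector("list", length(pieces))
  rem_list <- vector("list", length(pieces))
  disp <- NULL
  for (j in seq_along(pieces)) {
    idx <- pieces[[j]]
    txt <- sentences$text[idx]
    raw <- backend(txt, prompt = format_prompt(txt, config), config = config)
    res <- resolve_labels(parse_output(raw, length(txt)), txt,
                          backend, config)
    keep_rows <- sentences[idx[res$labels$index + 1L], , drop = FALSE]
    keep_rows$label <- res$labels$value
    keep_rows$na_subtype <- res$labels$na_subtype
    keep_rows$provenance <- res$labels$provenance
    lab_list[[j]] <- keep_rows
    if (nrow(res$removed)) {
      rem_rows <- sentences[idx[res$removed$index + 1L], , drop = FALSE]
      rem_rows$na_subtype <- res$removed$na_subtype
      rem_list[[j]] <- rem_rows
    }
    disp <- if (is.null(disp)) res$dispositions else disp + res$dispositions
  }
  list(labels = as.data.frame(data.table::rbindlist(lab_list)),
       removed = as.data.frame(data.table::rbindlist(rem_list)),
       dispositions = disp)
}

## --- validation metrics ----------------------------------------------------

#' F1 score from precision and recall
#'
#' @param precision,recall numeric vectors in \[0,1\].
#' @return `2PR/(P+R)`, with 0 where the denominator is 0.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Per-class and macro validation metrics
#'
#' One-vs-rest precision, recall and F1 per sentiment class plus their
#' unweighted macro averages.  Undefined ratios (an empty class) are
#' reported as 0 with the `undefined` flag set.
#'
#' @param gold,predicted aligned character vectors over the three classes.
#' @return object of class `nsr_validation`: list with `per_class` (data
#'   frame: class, n, precision, recall, f1, undefined) and `macro`
#'   (named vector).
#' @export
compute_validation_metrics <- function(gold, predicted) {
  stopifnot(length(gold) == length(predicted))
  rows <- lapply(SENTIMENT_CLASSES, function(cl) {
    tp <- sum(gold == cl & predicted == cl)
    fp <- sum(gold != cl & predicted == cl)
    fn <- sum(gold == cl & predicted != cl)
    undef <- (tp + fp == 0) || (tp + fn == 0)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    data.frame(class = cl, n = sum(gold == cl), precision = p, recall = r,
               f1 = f1_score(p, r), undefined = undef,
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  macro <- c(precision = mean(per_class$precision),
             recall = mean(per_class$recall),
             f1 = mean(per_class$f1))
  structure(list(per_class = per_class, macro = macro),
            class = "nsr_validation")
}

#' @export
print.nsr_validation <- function(x, ...) {
  df <- x$per_class
  df[c("precision", "recall", "f1")] <-
    round(df[c("precision", "recall", "f1")], 2)
  print(df, row.names = FALSE)
  cat(sprintf("Macro average: precision %.2f  recall %.2f  F1 %.2f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  invisible(x)
}
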
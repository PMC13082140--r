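## Note processing: section extraction, sentence splitting, clinical
## relevance filtering, and note-level inclusion filters.

.header_regex <- function(name) {
  sprintf("(?i)^[ \\t]*%s[ \\t]*(?::|$)", gsub(" ", "[ \\\\t]+", name))
}

## Locate all recognized section headers in a note.  Target headers open a
## section that is returned; boundary headers only terminate the previous
## section (the sectionizer knows many section titles, the analysis keeps
## four).  Headers match at line start, case-insensitively, followed by a
## colon or end of line.
.find_headers <- function(text) {
  hdr <- section_headers()
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  starts <- c(0L, cumsum(nchar(lines) + 1L))[seq_along(lines)]
  hits <- list()
  probe <- function(name, tag) {
    m <- regexpr(.header_regex(name), lines, perl = TRUE)
    idx <- which(m != -1L)
    if (length(idx))
      hits[[length(hits) + 1L]] <<- data.frame(
        line = idx, tag = tag,
        body_from = starts[idx] + attr(m, "match.length")[idx] + 1L,
        stringsAsFactors = FALSE)
  }
  for (tag in names(hdr$target))
    for (name in hdr$target[[tag]]) probe(name, tag)
  for (name in hdr$boundary) probe(name, NA_character_)
  if (!length(hits))
    return(data.frame(line = integer(), tag = character(),
                      body_from = integer()))
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out$line), , drop = FALSE]
  out[order(out$line), , drop = FALSE]
}

#' Extract the four analysis sections from a note
#'
#' Returns the free text between each recognized target header (Chief
#' Complaint, History of Present Illness, Mental Status Exam, Collateral)
#' and the next recognized header or the end of the note.  Other known
#' section headers (Plan, Medications, ...) act as boundaries only.  A note
#' with no recognized headers yields an empty result, not an error; such a
#' note is later dropped by the sentence-count filter.
#'
#' @param text full note body (character scalar).
#' @return named list mapping section tags (`CC`, `HPI`, `MSE`,
#'   `COLLATERAL`) to extracted text; absent sections are omitted.  Sections
#'   appear in note order.
#' @export
extract_sections <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) return(list())
  hd <- .find_headers(text)
  if (!nrow(hd)) return(list())
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  line_starts <- c(0L, cumsum(nchar(lines) + 1L))
  out <- list()
  for (i in seq_len(nrow(hd))) {
    tag <- hd$tag[i]
    if (is.na(tag) || !is.null(out[[tag]])) next   # boundary or repeat tag
    from <- hd$body_from[i]
    to <- if (i < nrow(hd)) line_starts[hd$line[i + 1L]] else nchar(text) + 1L
    span <- substr(text, from, to - 1L)
    out[[tag]] <- trimws(span)
  }
  out
}

#' Split section text into sentences
#'
#' Rule-based splitter: lines are treated as hard boundaries (clinical notes
#' are line-structured); within a line, splits after `.`, `!` or `?`
#' followed by whitespace, protecting common clinical abbreviations (Dr.,
#' Pt., e.g., a.m., numbered list markers).  Every non-whitespace character
#' of the input is covered by exactly one output sentence, and text without
#' terminal punctuation is emitted as a final fragment.
#'
#' @param text character scalar (one section's free text).
#' @return character vector of sentences, in order; empty input gives
#'   `character(0)`.
#' @export
sentencize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    prot <- gsub("(?i)\\b(e\\.g|i\\.e|a\\.m|p\\.m)\\.", "\\1\x01",
                 ln, perl = TRUE)
    prot <- gsub("(?i)\\b(Dr|Mr|Mrs|Ms|Pt|vs|etc|St|approx)\\.",
                 "\\1\x01", prot, perl = TRUE)
    prot <- gsub("^(\\s*[0-9]+)\\.", "\\1\x01", prot, perl = TRUE)
    parts <- strsplit(prot, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
    gsub("\x01", ".", parts, fixed = TRUE)
  })
  out <- trimws(unlist(out))
  out[nzchar(out)]
}

#' Flag clinically irrelevant sentences
#'
#' Heuristic stand-in for a trained clinical-relevance classifier, keyed to
#' its two dominant failure categories: contact/scheduling content (phone
#' numbers; call/fax/schedule/appointment language) and bare Mental Status
#' Exam template fields carrying no patient description.  Any classifier
#' honoring the same logical contract can replace it.
#'
#' @param text character vector of sentences.
#' @return logical vector, `TRUE` where the sentence is clinically relevant.
#' @export
is_relevant <- function(text) {
  phone <- grepl("[0-9]{3}[-.][0-9]{3}[-.][0-9]{4}", text) |
    grepl("\\b[0-9]{3}[-.][0-9]{4}\\b", text)
  contact <- grepl(
    "(?i)\\b(call|fax|schedule|scheduling|appointment|appointments)\\b",
    text, perl = TRUE)
  bare_field <- grepl("^[A-Za-z][A-Za-z /]{0,30}:\\s*$", text)
  !(phone | contact | bare_field)
}

#' Partition sentences into kept and dropped by clinical relevance
#'
#' @param sentences character vector, or a data frame with a `text` column.
#' @return list with `kept` and `dropped` (same type as the input).
#' @export
filter_relevant <- function(sentences) {
  txt <- if (is.data.frame(sentences)) sentences$text else sentences
  keep <- is_relevant(txt)
  if (is.data.frame(sentences))
    list(kept = sentences[keep, , drop = FALSE],
         dropped = sentences[!keep, , drop = FALSE])
  else
    list(kept = sentences[keep], dropped = sentences[!keep])
}

#' Note-level inclusion decision
#'
#' A note is dropped when its raw word count is below 500 or above 3000
#' (both bounds inclusive for keeping), or when fewer than 4 clinically
#' relevant sentences survive preprocessing.  The word count is computed on
#' the full raw note, not on the extracted sections.
#'
#' @param word_count whitespace-token count of the raw note.
#' @param n_sentences number of relevant sentences after filtering.
#' @return list with `keep` (logical) and `reason` (`"OK"`, `"MIN_WORDS"`,
#'   `"MAX_WORDS"`, or `"MIN_SENTENCES"`).
#' @export
apply_note_filters <- function(word_count, n_sentences) {
  if (word_count < 500) return(list(keep = FALSE, reason = "MIN_WORDS"))
  if (word_count > 3000) return(list(keep = FALSE, reason = "MAX_WORDS"))
  if (n_sentences < 4) return(list(keep = FALSE, reason = "MIN_SENTENCES"))
  list(keep = TRUE, reason = "OK")
}

#' Preprocess raw notes into the filtered sentence corpus
#'
#' Runs section extraction, sentence splitting and relevance filtering on
#' each note, then applies the note-level filters.
#'
#' @param notes data frame with `patient_id`, `text`, and optionally
#'   `encounter_id`; one note per row.
#' @return list with `sentences` (one row per sentence: `patient_id`,
#'   `section`, `index` within the note, `text`, `relevant`) and `notes`
#'   (one row per note: `patient_id`, `word_count`, `n_relevant`, `keep`,
#'   `reason`).  Sentence indices are contiguous per note over all
#'   extracted sentences, relevant or not.
#' @export
preprocess_notes <- function(notes) {
  stopifnot(is.data.frame(notes), all(c("patient_id", "text") %in%
                                        names(notes)))
  sent_list <- vector("list", nrow(notes))
  note_list <- vector("list", nrow(notes))
  for (i in seq_len(nrow(notes))) {
    secs <- extract_sections(notes$text[i])
    txt <- character(0); tag <- character(0)
    for (s in names(secs)) {
      ss <- sentencize(secs[[s]])
      txt <- c(txt, ss); tag <- c(tag, rep(s, length(ss)))
    }
    rel <- if (length(txt)) is_relevant(txt) else logical(0)
    wc <- count_words(notes$text[i])
    dec <- apply_note_filters(wc, sum(rel))
    if (length(txt))
      sent_list[[i]] <- data.frame(
        patient_id = notes$patient_id[i], section = tag,
        index = seq_along(txt) - 1L, text = txt, relevant = rel,
        stringsAsFactors = FALSE)
    note_list[[i]] <- data.frame(
      patient_id = notes$patient_id[i], word_count = wc,
      n_relevant = sum(rel), keep = dec$keep, reason = dec$reason,
      stringsAsFactors = FALSE)
  }
  list(sentences = as.data.frame(data.table::rbindlist(sent_list)),
       notes = as.data.frame(data.table::rbindlist(note_list)))
}
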
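test_that("prompts carry the required instructions", {
  p <- build_prompt()
  expect_match(p,
    "assign a sentiment score of negative, neutral, or positive",
    fixed = TRUE)
  s <- build_prompt(variant = "strict")
  expect_match(s, "JSON")
  expect_match(s, "exactly one")
  expect_error(format_prompt(character(0)), "empty")
})

test_that("parse_output classifies the documented subtype examples", {
  case <- function(raw, subtype) {
    p <- parse_output(raw, 1)
    expect_true(is.na(p$value))
    expect_identical(p$na_subtype, subtype)
  }
  case('{"0":"neutral-negative"}', "TWO_LABELS")
  case('{"sentence":"pt presents with distress"}', "ERROR")
  case('{"0":"neutral, explanation: factual description"}', "EXTRACT")
  case(paste0("I cannot analyze a sentence that contains information ",
              "about a patient's sexual assault."), "REFUSE")
  case("I'm unable to determine the sentiment from an incomplete sentence.",
       "E_TEXT")

  good <- parse_output('{"0":"negative","1":"Positive."}', 2)
  expect_identical(good$value, c("negative", "positive"))
  expect_true(all(good$na_subtype == "none"))
})

test_that("parser is total over random strings", {
  set.seed(5)
  raws <- random_raw_strings(500)
  for (r in raws) {
    p <- parse_output(r, 2)
    expect_identical(nrow(p), 2L)
    labeled <- !is.na(p$value) & p$na_subtype == "none"
    na_ok <- is.na(p$value) & p$na_subtype %in% nsrbias:::NA_SUBTYPES
    expect_true(all(labeled | na_ok))
  }
})

test_that("recover_extract agrees with a brute-force substring oracle", {
  expect_identical(
    recover_extract("neutral, explanation: factual")$value, "neutral")
  expect_identical(
    recover_extract("both positive and negative here")$subtype,
    "TWO_LABELS")
  expect_identical(recover_extract("Negative.")$value, "negative")
  expect_true(is.na(recover_extract("nothing useful")$value))

  set.seed(6)
  words <- c("negative", "Positive", "NEUTRAL", "note", "feels", "pt",
             "negatively", "positives")
  for (i in 1:200) {
    s <- paste(sample(words, sample(1:6, 1), replace = TRUE),
               collapse = " ")
    found <- oracle_sentiments_present(s)
    rec <- recover_extract(s)
    if (length(found) == 1) expect_identical(rec$value, found)
    else if (length(found) >= 2) expect_identical(rec$subtype, "TWO_LABELS")
    else expect_true(is.na(rec$value))
  }
})

test_that("resolve_labels recovers, reruns once, and conserves counts", {
  txts <- c("Pt was agitated and yelling at staff in the waiting area.",
            "Pt denies suicidal ideation at this time.",
            "Pt was cooperative and pleasant during the interview.")
  raw <- lexicon_backend(txts)
  parsed <- parse_output(raw, 3)
  res <- resolve_labels(parsed, txts)
  expect_identical(res$labels$value, c("negative", "neutral", "positive"))
  expect_true(all(res$labels$provenance == "first_pass"))

  ## one REFUSE sentence: rerun through the backend resolves it
  parsed2 <- parsed
  parsed2$value[1] <- NA; parsed2$na_subtype[1] <- "REFUSE"
  res2 <- resolve_labels(parsed2, txts)
  expect_identical(res2$labels$value[1], "negative")
  expect_identical(res2$labels$provenance[1], "rerun")

  ## backend failure on rerun: sentence retained as NA, with a warning
  broken <- function(sentences, prompt, config) stop("backend down")
  expect_warning(res3 <- resolve_labels(parsed2, txts, backend = broken),
                 "backend failure")
  expect_true(is.na(res3$labels$value[1]))
  expect_identical(res3$labels$provenance[1], "unresolved")
  d <- res3$dispositions
  expect_identical(unname(d["input"]), unname(sum(d[-1])))
})

test_that("chaos batches resolve to planted dispositions and labels", {
  sc <- tiny_scenario()
  sc$note_profile$chaos <- setNames(c(0.05, 0.05, 0.1, 0.05, 0.08),
                                    nsrbias:::NA_SUBTYPES)
  g <- generate_cohort(sc)
  nt <- generate_notes(g$cohort, sc)
  tr <- nt$truth[!nt$truth$is_filler, ]
  raws <- generate_raw_labeler_outputs(tr, sc, seed = 9)
  parsed <- do.call(rbind,
                    lapply(raws$raw, parse_output, batch_size = 1))
  expect_identical(
    ifelse(parsed$na_subtype == "none", "none", parsed$na_subtype),
    ifelse(raws$gold_subtype == "none", "none", raws$gold_subtype))
  res <- resolve_labels(parsed, raws$text)
  expect_identical(unname(res$dispositions["removed_e_text"]),
                   sum(raws$gold_subtype == "E_TEXT"))
  kept_gold <- raws$gold_label[raws$gold_subtype != "E_TEXT"]
  expect_identical(res$labels$value, kept_gold)
})

test_that("lexicon backend is deterministic and cue-driven", {
  expect_identical(lexicon_classify("He remains noncompliant with meds."),
                   "negative")
  expect_identical(lexicon_classify("Pt was cooperative today."),
                   "positive")
  expect_identical(lexicon_classify("Pt lives nearby."), "neutral")
  expect_identical(lexicon_backend(c("a", "b")),
                   lexicon_backend(c("a", "b")))
})

test_that("validation metrics match the brute-force oracle", {
  set.seed(7)
  classes <- c("negative", "neutral", "positive")
  for (i in 1:50) {
    n <- sample(5:80, 1)
    gold <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    m <- compute_validation_metrics(gold, pred)
    o <- oracle_metrics(gold, pred)
    expect_equal(m$per_class$precision, unname(o$precision),
                 tolerance = 1e-12)
    expect_equal(m$per_class$recall, unname(o$recall), tolerance = 1e-12)
    expect_equal(m$per_class$f1, unname(o$f1), tolerance = 1e-12)
    expect_equal(unname(m$macro), unname(o$macro), tolerance = 1e-12)
  }
  ident <- compute_validation_metrics(gold, gold)
  expect_true(all(ident$per_class[c("precision", "recall", "f1")] == 1))

  ## empty predicted class: reported as 0 with the undefined flag
  m0 <- compute_validation_metrics(c("negative", "neutral"),
                                   c("neutral", "neutral"))
  pos <- m0$per_class[m0$per_class$class == "positive", ]
  expect_identical(pos$precision, 0)
  expect_true(pos$undefined)
})

test_that("with the lexicon backend and chaos off, predictions equal gold", {
  sc <- tiny_scenario(n = 20, seed = 43)
  g <- generate_cohort(sc)
  nt <- generate_notes(g$cohort, sc)
  res <- run_pipeline(nt$notes)
  m <- merge(res$labels, nt$truth, by = c("patient_id", "index"))
  expect_identical(nrow(m), nrow(res$labels))
  expect_identical(m$label, m$gold_label)
  expect_identical(unname(res$dispositions["retained_na"]), 0L)
})
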
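## Synthetic cohort and note generation.
##
## Everything downstream of this module (sectionizer, sentencizer, relevance
## filter, labeler, NSR, regressions) is tested against the ground truth
## recorded here: gold sentiment per sentence, the per-patient negative
## propensity, and the linear predictor and outcome draw per diagnosis.

## Linear predictor for one outcome's semantic coefficient list, evaluated
## on a cohort data frame with treatment coding (White / Female reference).
linpred_from_coeffs <- function(cc, df) {
  rlook <- function(v) {
    out <- unname(v[match(df$race_ethnicity, names(v))])
    out[is.na(out)] <- 0
    out
  }
  male <- as.integer(df$sex == "Male")
  t <- as.integer(df$trauma_history)
  s <- as.integer(df$substance_history)
  cc$age * df$age + cc$male * male + rlook(cc$race) +
    cc$ses * df$ses_z + cc$trauma * t + cc$substance * s +
    cc$trauma_substance * t * s +
    rlook(cc$race_male) * male + rlook(cc$race_ses) * df$ses_z +
    cc$male_ses * male * df$ses_z + rlook(cc$race_male_ses) * male * df$ses_z +
    cc$nsr * df$nsr + rlook(cc$nsr_race) * df$nsr +
    cc$nsr_male * df$nsr * male + cc$nsr_ses * df$nsr * df$ses_z
}

.category_for_diagnosis <- c(
  Anxiety = "Anxiety and fear-related disorders",
  Bipolar = "Bipolar and related disorders",
  Depression = "Depressive disorders",
  Trauma = "Trauma- and stressor-related disorders",
  SCZ = "Schizophrenia spectrum and other psychotic disorders"
)

.sample_codes <- function(category, n, ccsr) {
  codes <- ccsr$icd10[ccsr$category == category]
  if (!length(codes)) stop("no packaged ICD-10 codes for category: ", category)
  sample(codes, n, replace = TRUE)
}

#' Generate a synthetic patient cohort
#'
#' Draws demographics from the scenario's group mix, assigns zip codes from
#' the packaged synthetic zip-to-income table, draws the per-patient negative
#' sentence propensity (the true NSR expectation) from the configured Beta
#' law, and samples diagnosis indicators from the configured logistic models.
#' An intercept left `NA` is centered so that the mean linear predictor hits
#' the logit of the outcome's target prevalence.
#'
#' @param scenario an `nsr_scenario` from [scenario()] or [scenario_config()].
#' @param seed optional seed overriding `scenario$seed`.
#' @return list with `cohort` (data frame, one row per patient) and `truth`
#'   (resolved coefficients and linear predictors per outcome).
#' @export
generate_cohort <- function(scenario, seed = NULL) {
  validate_scenario(scenario)
  set.seed(seed %||% scenario$seed)
  n <- scenario$n_patients
  zip_tab <- load_zip_income()

  race <- sample(RACE_LEVELS, n, replace = TRUE,
                 prob = scenario$group_mix$race[RACE_LEVELS])
  sex <- ifelse(runif(n) < scenario$group_mix$p_male, "Male", "Female")
  ad <- scenario$age_dist
  age <- as.integer(round(pmin(pmax(rnorm(n, ad$mean, ad$sd), ad$min),
                               ad$max)))
  zip <- sample(zip_tab$zip, n, replace = TRUE)
  ses <- map_ses(zip, zip_tab)
  trauma_history <- runif(n) < scenario$history_rates$trauma
  substance_history <- runif(n) < scenario$history_rates$substance

  encounter_date <- as.Date("2012-01-01") +
    sample.int(as.integer(as.Date("2023-10-31") - as.Date("2012-01-01")),
               n, replace = TRUE)
  birth_date <- as.Date(sprintf(
    "%04d-%02d-%02d",
    as.integer(format(encounter_date, "%Y")) - age,
    as.integer(format(encounter_date, "%m")),
    pmin(as.integer(format(encounter_date, "%d")), 28L)
  ))

  if (!is.null(scenario$cohort_groups)) {
    gsizes <- vapply(scenario$cohort_groups, function(g) as.integer(g$n), 1L)
    stopifnot(sum(gsizes) == n)
    group <- rep(names(gsizes), times = gsizes)
    nsr <- numeric(n)
    for (g in names(gsizes)) {
      sh <- beta_shapes(scenario$cohort_groups[[g]]$nsr_mean,
                        scenario$cohort_groups[[g]]$nsr_sd)
      nsr[group == g] <- rbeta(gsizes[[g]], sh[1], sh[2])
    }
  } else {
    group <- NA_character_
    sh <- beta_shapes(scenario$nsr_dist$mean, scenario$nsr_dist$sd)
    nsr <- rbeta(n, sh[1], sh[2])
  }

  cohort <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    sex = sex, race_ethnicity = race, age = age,
    birth_date = birth_date, encounter_date = encounter_date,
    zip = zip, ses = ses,
    trauma_history = trauma_history, substance_history = substance_history,
    nsr = nsr, cohort_group = group,
    stringsAsFactors = FALSE
  )
  cohort$ses_z <- as.numeric(scale(cohort$ses))

  truth <- list(coeffs = scenario$diag_coeffs, lp = list())
  for (d in names(scenario$diag_coeffs)) {
    cc <- scenario$diag_coeffs[[d]]
    lp_rest <- linpred_from_coeffs(cc, cohort)
    if (is.na(cc$intercept))
      cc$intercept <- qlogis(cc$target_prev) - mean(lp_rest)
    lp <- cc$intercept + lp_rest
    cohort[[paste0("dx_", tolower(d))]] <-
      as.integer(runif(n) < plogis(lp))
    truth$coeffs[[d]] <- cc
    truth$lp[[d]] <- lp
  }

  if (!is.null(scenario$cohort_groups)) {
    cohort$outcome <- as.integer(cohort$cohort_group == "SCZ")
    cohort$control_category <-
      ifelse(cohort$outcome == 1L, "none", "Depression")
  } else if ("dx_scz" %in% names(cohort)) {
    cohort$outcome <- cohort$dx_scz
    ctl <- setdiff(names(scenario$diag_coeffs), "SCZ")
    cohort$control_category <- "none"
    if (length(ctl)) {
      ctl_mat <- as.matrix(cohort[paste0("dx_", tolower(ctl))])
      pick <- apply(ctl_mat, 1, function(r) {
        pos <- which(r == 1L)
        if (length(pos)) ctl[pos[sample.int(length(pos), 1)]] else "none"
      })
      cohort$control_category <- ifelse(cohort$outcome == 1L, "none", pick)
    }
  }

  ## Primary ICD-10 code consistent with the assigned cohort, drawn from the
  ## packaged CCSR subset; patients with no qualifying diagnosis receive an
  ## unmapped wellness code and are excluded by the cohort builder.
  if ("outcome" %in% names(cohort)) {
    ccsr <- load_ccsr()
    code <- rep("Z00.0", n)
    scz_idx <- which(cohort$outcome == 1L)
    if (length(scz_idx))
      code[scz_idx] <- .sample_codes(.category_for_diagnosis[["SCZ"]],
                                     length(scz_idx), ccsr)
    for (d in setdiff(unique(cohort$control_category), "none")) {
      idx <- which(cohort$outcome == 0L & cohort$control_category == d)
      if (length(idx))
        code[idx] <- .sample_codes(.category_for_diagnosis[[d]],
                                   length(idx), ccsr)
    }
    cohort$primary_code <- code
  }

  list(cohort = cohort, truth = truth)
}

#' Generate a pre-index diagnosis history table
#'
#' Emits dated ICD-10 rows consistent with the cohort's trauma/substance
#' history flags (strictly before the encounter date), so the cohort
#' builder's derived flags can be compared to generator truth exactly.
#'
#' @param cohort cohort data frame from [generate_cohort()].
#' @param seed random seed.
#' @return data frame with `patient_id`, `code`, `date`.
#' @export
generate_dx_history <- function(cohort, seed = 1L) {
  set.seed(seed)
  ccsr <- load_ccsr()
  substance_cats <- unique(ccsr$category[ccsr$group == "substance"])
  rows <- list()
  add <- function(pid, cat, date) {
    data.frame(patient_id = pid, code = .sample_codes(cat, length(pid), ccsr),
               date = date, stringsAsFactors = FALSE)
  }
  tr <- cohort$trauma_history
  if (any(tr))
    rows$trauma <- add(cohort$patient_id[tr],
                       "Trauma- and stressor-related disorders",
                       cohort$encounter_date[tr] -
                         sample(30:2000, sum(tr), replace = TRUE))
  su <- cohort$substance_history
  if (any(su)) {
    pid <- cohort$patient_id[su]
    cat <- sample(substance_cats, sum(su), replace = TRUE)
    rows$substance <- data.frame(
      patient_id = pid,
      code = vapply(cat, function(cc) .sample_codes(cc, 1L, ccsr), ""),
      date = cohort$encounter_date[su] -
        sample(30:2000, sum(su), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  ## post-index noise: never adds SCZ codes to controls so that cohort
  ## assignment ("never obtained a SCZ diagnosis") stays consistent
  noise <- runif(nrow(cohort)) < 0.2
  if (any(noise)) {
    pid <- cohort$patient_id[noise]
    cat <- sample(c("Anxiety and fear-related disorders",
                    "Depressive disorders"), sum(noise), replace = TRUE)
    rows$noise <- data.frame(
      patient_id = pid,
      code = vapply(cat, function(cc) .sample_codes(cc, 1L, ccsr), ""),
      date = cohort$encounter_date[noise] +
        sample(1:400, sum(noise), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic ED psychiatric notes with gold sentence labels
#'
#' Each note contains the four analysis sections (Chief Complaint, History
#' of Present Illness, Mental Status Exam, Collateral) built from sentiment
#' template banks, contact/scheduling filler at the configured rate, and a
#' trailing Plan section padded so the raw word count lands in the
#' scenario's `word_range`.  Negative sentences are planted per patient with
#' probability equal to the patient's true NSR expectation.
#'
#' @param cohort cohort data frame from [generate_cohort()].
#' @param scenario the generating `nsr_scenario`.
#' @param seed optional seed overriding `scenario$seed + 1`.
#' @return list with `notes` (one row per note: `patient_id`, `encounter_id`,
#'   `encounter_date`, `note_type`, `text`, `word_count`) and `truth`
#'   (one row per planted sentence: section, index, text, `gold_label`,
#'   `is_filler`).
#' @export
generate_notes <- function(cohort, scenario, seed = NULL) {
  set.seed(seed %||% (scenario$seed + 1L))
  np <- scenario$note_profile
  tpl <- note_templates()
  n <- nrow(cohort)

  n_rel <- pmin(pmax(rnbinom(n, mu = np$sentence_mean,
                             size = np$sentence_size),
                     np$min_sentences), np$max_sentences)
  n_fill <- rbinom(n, n_rel, np$irrelevant_rate)
  targets <- sample(np$word_range[1]:np$word_range[2], n, replace = TRUE)

  notes <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_rel[i]
    lab <- ifelse(runif(k) < cohort$nsr[i], "negative",
                  ifelse(runif(k) < np$pos_share, "positive", "neutral"))
    txt <- character(k)
    for (cl in c("negative", "neutral", "positive")) {
      idx <- which(lab == cl)
      if (length(idx))
        txt[idx] <- sample(tpl[[cl]], length(idx), replace = TRUE)
    }
    total <- k + n_fill[i]
    fill_pos <- if (n_fill[i] > 0) sort(sample.int(total, n_fill[i]))
                else integer(0)
    all_txt <- character(total); all_lab <- character(total)
    all_txt[fill_pos] <- sample(tpl$filler, n_fill[i], replace = TRUE)
    all_lab[fill_pos] <- NA_character_
    all_txt[setdiff(seq_len(total), fill_pos)] <- txt
    all_lab[setdiff(seq_len(total), fill_pos)] <- lab

    ## contiguous section blocks in fixed note order
    n_cc <- min(2L, total)
    rest <- total - n_cc
    n_hpi <- round(rest * 0.45); n_mse <- round(rest * 0.35)
    n_col <- rest - n_hpi - n_mse
    sect <- c(rep("CC", n_cc), rep("HPI", n_hpi),
              rep("MSE", n_mse), rep("COLLATERAL", n_col))

    block <- function(s) paste(all_txt[sect == s], collapse = "\n")
    body <- paste0(
      "ED Psychiatric Note\n",
      "Encounter Date: ", format(cohort$encounter_date[i]), "\n",
      "Chief Complaint:\n", block("CC"), "\n",
      "History of Present Illness:\n", block("HPI"), "\n",
      "Mental Status Exam:\n", block("MSE"), "\n",
      "Collateral:\n", block("COLLATERAL"), "\n"
    )
    wc <- count_words(body)
    deficit <- targets[i] - wc - 1L   # +1 for the Plan: header token
    if (deficit > 0) {
      ## greedy fill: stop at the first sentence that reaches the target so
      ## the overshoot never exceeds one padding sentence
      pool <- sample(tpl$padding, ceiling(deficit / 7) + 10, replace = TRUE)
      cum <- cumsum(count_words(pool))
      while (cum[length(cum)] < deficit) {
        pool <- c(pool, sample(tpl$padding, 5, replace = TRUE))
        cum <- cumsum(count_words(pool))
      }
      pad <- pool[seq_len(which(cum >= deficit)[1])]
      body <- paste0(body, "Plan:\n", paste(pad, collapse = "\n"), "\n")
    }
    notes[[i]] <- data.frame(
      patient_id = cohort$patient_id[i],
      encounter_id = paste0("E", cohort$patient_id[i]),
      encounter_date = cohort$encounter_date[i],
      note_type = "ED Psychiatric Note",
      text = body, word_count = count_words(body),
      stringsAsFactors = FALSE
    )
    truths[[i]] <- data.frame(
      patient_id = cohort$patient_id[i],
      section = sect, index = seq_len(total) - 1L,
      text = all_txt, gold_label = all_lab,
      is_filler = is.na(all_lab),
      stringsAsFactors = FALSE
    )
  }
  list(notes = as.data.frame(data.table::rbindlist(notes)),
       truth = as.data.frame(data.table::rbindlist(truths)))
}

#' Generate raw labeler output strings with configured malformation rates
#'
#' Emits one raw output string per sentence (single-sentence batches keyed
#' `"0"`).  Clean outputs are well-formed JSON label maps; at the scenario's
#' chaos rates, outputs instead exemplify the five unlabelable subtypes
#' (TWO_LABELS, ERROR, EXTRACT, REFUSE, E_TEXT), with the gold subtype
#' recorded.
#'
#' @param sentences data frame with a `text` column and optionally
#'   `gold_label`.
#' @param scenario the generating `nsr_scenario` (chaos rates read from
#'   `note_profile$chaos`).
#' @param seed random seed.
#' @return data frame with `text`, `gold_label`, `raw`, `gold_subtype`.
#' @export
generate_raw_labeler_outputs <- function(sentences, scenario, seed = 1L) {
  set.seed(seed)
  chaos <- scenario$note_profile$chaos
  if (sum(chaos) > 1)
    stop_config("note_profile$chaos", "rates must sum to at most 1")
  n <- nrow(sentences)
  gold <- sentences$gold_label %||% rep(NA_character_, n)
  miss <- is.na(gold)
  if (any(miss))
    gold[miss] <- lexicon_classify(sentences$text[miss])

  subtype <- sample(c(NA_SUBTYPES, "none"), n, replace = TRUE,
                    prob = c(chaos, 1 - sum(chaos)))
  raw <- sprintf('{"0":"%s"}', gold)
  raw[subtype == "TWO_LABELS"] <- '{"0":"neutral-negative"}'
  raw[subtype == "ERROR"] <- '{"sentence":"pt presents with distress"}'
  ex <- subtype == "EXTRACT"
  raw[ex] <- sprintf(
    '{"0":"%s, explanation: reading this description feels %s to me"}',
    gold[ex], gold[ex])
  raw[subtype == "REFUSE"] <- paste0(
    "I cannot analyze a sentence that contains information about a ",
    "patient's sexual assault.")
  raw[subtype == "E_TEXT"] <- paste0(
    "I'm unable to determine the sentiment from an incomplete sentence.")

  data.frame(text = sentences$text, gold_label = gold, raw = raw,
             gold_subtype = subtype, stringsAsFactors = FALSE)
}
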
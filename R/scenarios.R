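## Scenario configurations for the synthetic-data module.
##
## A scenario is the complete "stated world" for one simulation: cohort
## composition, covariate distributions, per-patient negative-sentence
## propensity (the quantity the NSR estimates), diagnosis models on the
## log-odds scale, and the note profile (sentence counts, filler rate,
## malformed-labeler-output rates).

RACE_LEVELS <- c("White", "Asian", "Black", "Hispanic or Latino",
                 "Multiracial", "Some Other Race")
SEX_LEVELS <- c("Female", "Male")
DIAGNOSES <- c("Anxiety", "Bipolar", "Depression", "Trauma", "SCZ")
NA_SUBTYPES <- c("TWO_LABELS", "ERROR", "EXTRACT", "REFUSE", "E_TEXT")

## Published cohort margins used as generator defaults: sample sizes
## 20891 controls / 8114 SCZ; group NSR means (SD) 0.22 (0.13) / 0.28 (0.14);
## race/ethnicity and sex counts pooled over both groups.
.cohort_margins <- function() {
  n_ctl <- 20891; n_scz <- 8114; n <- n_ctl + n_scz
  race_counts <- c(
    "White" = 5450 + 1429, "Asian" = 701 + 274, "Black" = 5991 + 3340,
    "Hispanic or Latino" = 4221 + 1284, "Multiracial" = 419 + 153,
    "Some Other Race" = 4109 + 1634
  )
  m <- (n_ctl * 0.22 + n_scz * 0.28) / n
  v_within <- (n_ctl * 0.13^2 + n_scz * 0.14^2) / n
  v_between <- (n_ctl * (0.22 - m)^2 + n_scz * (0.28 - m)^2) / n
  list(
    race = race_counts / n,
    p_male = (10463 + 4883) / n,
    age = list(mean = (n_ctl * 36.3 + n_scz * 40.7) / n, sd = 16.7),
    nsr_pooled = list(mean = m, sd = sqrt(v_within + v_between)),
    nsr_scz = list(mean = 0.28, sd = 0.14),
    nsr_control = list(mean = 0.22, sd = 0.13),
    p_trauma_history = (11463 + 1186) / n,
    p_substance_history = (2513 + 998) / n,
    p_scz = n_scz / n
  )
}

.default_note_profile <- function() {
  list(
    sentence_mean = 28, sentence_size = 13,
    min_sentences = 8, max_sentences = 60,
    pos_share = 0.25,            # share of non-negative sentences positive
    irrelevant_rate = 0.10,
    word_range = c(550L, 1100L),
    chaos = setNames(rep(0, 5), NA_SUBTYPES)
  )
}

#' Construct and validate a scenario configuration
#'
#' Most users want the packaged scenarios via [scenario()]; this constructor
#' validates a configuration assembled field by field.
#'
#' @param name scenario identifier.
#' @param n_patients number of patients to generate.
#' @param seed default random seed for the scenario.
#' @param group_mix list with `race` (named probabilities over the six
#'   race/ethnicity categories) and `p_male`.
#' @param age_dist list with `mean`, `sd`, `min`, `max` (years).
#' @param nsr_dist list with `mean` and `sd` of the per-patient negative
#'   sentence propensity (moment-matched to a Beta law), or per-group when
#'   `cohort_groups` is set.
#' @param diag_coeffs named list (one entry per outcome) of log-odds
#'   coefficient lists; see [scenario()] for the packaged shapes.
#' @param cohort_groups optional named list assigning fixed group sizes and
#'   per-group NSR moments (used by the note-pipeline scenario).
#' @param note_profile note-generation parameters; see
#'   `nsrbias:::.default_note_profile` for the fields and defaults.
#' @param history_rates list with pre-index `trauma` and `substance`
#'   diagnosis-history probabilities.
#' @return object of class `nsr_scenario`.
#' @export
scenario_config <- function(name, n_patients, seed,
                            group_mix = NULL, age_dist = NULL,
                            nsr_dist = NULL, diag_coeffs = list(),
                            cohort_groups = NULL,
                            note_profile = NULL,
                            history_rates = NULL) {
  m <- .cohort_margins()
  group_mix <- group_mix %||% list(race = m$race, p_male = m$p_male)
  age_dist <- age_dist %||% list(mean = m$age$mean, sd = m$age$sd,
                                 min = 1, max = 100)
  nsr_dist <- nsr_dist %||% m$nsr_pooled
  note_profile <- utils::modifyList(.default_note_profile(),
                                    note_profile %||% list())
  history_rates <- history_rates %||% list(trauma = m$p_trauma_history,
                                           substance = m$p_substance_history)

  sc <- structure(list(
    name = name, n_patients = as.integer(n_patients), seed = as.integer(seed),
    group_mix = group_mix, age_dist = age_dist, nsr_dist = nsr_dist,
    diag_coeffs = diag_coeffs, cohort_groups = cohort_groups,
    note_profile = note_profile, history_rates = history_rates
  ), class = "nsr_scenario")
  validate_scenario(sc)
  sc
}

#' @rdname scenario_config
#' @param scenario an `nsr_scenario` object.
#' @export
validate_scenario <- function(scenario) {
  sc <- scenario
  if (sc$n_patients < 1) stop_config("n_patients", "must be >= 1")
  pr <- sc$group_mix$race
  if (is.null(names(pr)) || !setequal(names(pr), RACE_LEVELS))
    stop_config("group_mix$race", "must name all six race/ethnicity levels")
  if (any(pr < 0) || abs(sum(pr) - 1) > 1e-8)
    stop_config("group_mix$race", "probabilities must be >= 0 and sum to 1")
  if (sc$group_mix$p_male < 0 || sc$group_mix$p_male > 1)
    stop_config("group_mix$p_male", "must lie in [0,1]")
  if (sc$age_dist$min < 1 || sc$age_dist$max > 100 ||
      sc$age_dist$min > sc$age_dist$max)
    stop_config("age_dist", "bounds must satisfy 1 <= min <= max <= 100")
  np <- sc$note_profile
  if (np$pos_share < 0 || np$pos_share > 1)
    stop_config("note_profile$pos_share", "must lie in [0,1]")
  if (np$irrelevant_rate < 0 || np$irrelevant_rate > 1)
    stop_config("note_profile$irrelevant_rate", "must lie in [0,1]")
  if (!setequal(names(np$chaos), NA_SUBTYPES))
    stop_config("note_profile$chaos", "must name the five NA subtypes")
  if (any(np$chaos < 0) || sum(np$chaos) > 1)
    stop_config("note_profile$chaos",
                "rates must be >= 0 and sum to at most 1")
  if (is.null(sc$cohort_groups)) {
    beta_shapes(sc$nsr_dist$mean, sc$nsr_dist$sd)  # errors if infeasible
  } else {
    for (g in sc$cohort_groups)
      beta_shapes(g$nsr_mean, g$nsr_sd)
  }
  invisible(sc)
}

## Empty (all-zero) semantic coefficient list for one outcome.
.zero_coeffs <- function() {
  rc <- setNames(rep(0, 5), setdiff(RACE_LEVELS, "White"))
  list(intercept = NA_real_, target_prev = 0.5,
       age = 0, male = 0, race = rc, ses = 0,
       trauma = 0, substance = 0, trauma_substance = 0,
       race_male = rc, race_ses = rc, male_ses = 0, race_male_ses = rc,
       nsr = 0, nsr_race = rc, nsr_male = 0, nsr_ses = 0)
}

#' Packaged simulation scenarios
#'
#' * `"table3"`: one cohort with per-patient NSR drawn from a Beta law
#'   moment-matched to the pooled published group moments, and five
#'   independent diagnosis indicators whose log-odds are linear in the NSR
#'   with the published univariate odds ratios (Anxiety 0.73, Bipolar 1.15,
#'   Depression 1.41, Trauma 0.51, SCZ 1.80) as generating slopes.
#' * `"table2"`: two fixed note groups (SCZ / Control) whose per-patient
#'   negative-sentence propensities follow Beta laws matched to the group
#'   NSR moments 0.28 (0.14) and 0.22 (0.13); drives the end-to-end note
#'   pipeline.
#' * `"model1"`: a single SCZ outcome generated from the full interaction
#'   model (age, sex, race/ethnicity, standardized SES, trauma and substance
#'   history and their interaction, NSR and its race/sex/SES interactions)
#'   with published effects (NSR OR 1.34, Male OR 1.14, Black x Male 1.08,
#'   Asian x Male 1.20, Trauma x Substance 1.11) as generating values.
#'
#' @param name one of `"table2"`, `"table3"`, `"model1"`.
#' @param n_patients override the scenario's default size (for `"table2"`,
#'   patients per group).
#' @param seed override the scenario's default seed.
#' @return an `nsr_scenario`.
#' @export
scenario <- function(name = c("table2", "table3", "model1"),
                     n_patients = NULL, seed = NULL) {
  name <- match.arg(name)
  m <- .cohort_margins()
  switch(name,
    table3 = {
      ## Generating odds ratios per unit NSR and target marginal
      ## prevalences (SCZ share is published; control-category shares are
      ## not and are a documented package choice).
      ors <- c(Anxiety = 0.73, Bipolar = 1.15, Depression = 1.41,
               Trauma = 0.51, SCZ = 1.80)
      prev <- c(Anxiety = 0.22, Bipolar = 0.11, Depression = 0.22,
                Trauma = 0.17, SCZ = m$p_scz)
      dc <- lapply(DIAGNOSES, function(d) {
        z <- .zero_coeffs(); z$nsr <- log(ors[[d]]); z$target_prev <- prev[[d]]
        z
      })
      names(dc) <- DIAGNOSES
      scenario_config("table3", n_patients %||% 50000L, seed %||% 42L,
                      diag_coeffs = dc)
    },
    table2 = {
      npg <- n_patients %||% 2000L
      groups <- list(
        SCZ = list(n = npg, nsr_mean = m$nsr_scz$mean,
                   nsr_sd = m$nsr_scz$sd),
        Control = list(n = npg, nsr_mean = m$nsr_control$mean,
                       nsr_sd = m$nsr_control$sd)
      )
      scenario_config("table2", 2L * npg, seed %||% 7L,
                      cohort_groups = groups)
    },
    model1 = {
      z <- .zero_coeffs()
      z$target_prev <- m$p_scz
      z$age <- 0.0025                      # OR about 1.0025 per year
      z$male <- log(1.14)
      z$trauma <- log(0.25)                # strong negative, per group split
      z$substance <- log(0.80)
      z$trauma_substance <- log(1.11)
      z$race_male[["Black"]] <- log(1.08)
      z$race_male[["Asian"]] <- log(1.20)
      z$race_ses[c("Black", "Hispanic or Latino", "Some Other Race")] <- 0.08
      z$race_male_ses[c("Asian", "Black")] <- -0.10
      z$nsr <- log(1.34)
      z$nsr_race[c("Black", "Hispanic or Latino", "Some Other Race")] <-
        c(0.30, 0.25, 0.25)
      scenario_config("model1", n_patients %||% 100000L, seed %||% 42L,
                      diag_coeffs = list(SCZ = z))
    }
  )
}

#' Read or write a scenario as JSON
#'
#' @param path file path.
#' @param scenario an `nsr_scenario`.
#' @return `read_scenario` returns an `nsr_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  jsonlite::write_json(unclass(scenario), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  relist_num <- function(v) if (is.list(v)) unlist(v) else v
  x$group_mix$race <- relist_num(x$group_mix$race)
  x$note_profile$chaos <- relist_num(x$note_profile$chaos)
  x$note_profile$word_range <- as.integer(x$note_profile$word_range)
  x$diag_coeffs <- lapply(x$diag_coeffs, function(cc) {
    for (f in c("race", "race_male", "race_ses", "race_male_ses", "nsr_race"))
      cc[[f]] <- relist_num(cc[[f]])
    cc
  })
  do.call(scenario_config,
          x[c("name", "n_patients", "seed", "group_mix", "age_dist",
              "nsr_dist", "diag_coeffs", "cohort_groups", "note_profile",
              "history_rates")])
}

#' @export
print.nsr_scenario <- function(x, ...) {
  cat(sprintf("<nsr_scenario '%s'>  n_patients=%d  seed=%d\n",
              x$name, x$n_patients, x$seed))
  if (!is.null(x$cohort_groups))
    cat("  groups:", paste(names(x$cohort_groups), collapse = ", "), "\n")
  if (length(x$diag_coeffs))
    cat("  outcomes:", paste(names(x$diag_coeffs), collapse = ", "), "\n")
  invisible(x)
}
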
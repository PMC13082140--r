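## Cohort builder: CCSR-based cohort assignment, covariate derivation,
## race/ethnicity harmonization, SES mapping, and patient-level exclusions.

#' Load the packaged CCSR subset
#'
#' A documented subset of the Clinical Classifications Software Refined
#' (CCSR) ICD-10 grouping, spanning the schizophrenia-spectrum category,
#' the four control categories, and the nine substance-related categories
#' used for the history flags.  A full CCSR file with the same columns
#' (`icd10`, `category`, `group`) can be supplied through `path`.
#'
#' @param path optional path to an alternative CCSR CSV.
#' @return data frame with `icd10`, `category`, `group`.
#' @export
load_ccsr <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ccsr_subset.csv",
                                package = "nsrbias", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("icd10", "category", "group") %in% names(df)))
  if (anyDuplicated(df$icd10))
    stop("CCSR map assigns more than one category to a code")
  df
}

SES_RANGE <- c(21846, 250000)

#' Load the synthetic zip-to-income lookup table
#'
#' Synthetic stand-in for census median-household-income data: 100 zip
#' codes whose incomes span the published range $21,846-$250,000.  Values
#' outside that range fail load-time validation.
#'
#' @param path optional path to an alternative lookup CSV (`zip`, `income`).
#' @return data frame with `zip` (character) and `income` (USD).
#' @export
load_zip_income <- function(path = NULL) {
  path <- path %||% system.file("extdata", "zip_income_synthetic.csv",
                                package = "nsrbias", mustWork = TRUE)
  df <- utils::read.csv(path, colClasses = c(zip = "character"),
                        stringsAsFactors = FALSE)
  stopifnot(all(c("zip", "income") %in% names(df)))
  if (any(df$income < SES_RANGE[1] | df$income > SES_RANGE[2]))
    stop("zip-income table contains values outside $",
         SES_RANGE[1], "-$", SES_RANGE[2])
  df
}

#' Map zip codes to median household income
#'
#' @param zip_code character vector of zip codes.
#' @param lookup lookup table from [load_zip_income()].
#' @return numeric incomes; `NA` where the zip is missing from the table
#'   (the patient is then excluded with reason `MISSING_SES`).
#' @export
map_ses <- function(zip_code, lookup = load_zip_income()) {
  lookup$income[match(as.character(zip_code), lookup$zip)]
}

CONTROL_CATEGORIES <- c(
  Anxiety = "Anxiety and fear-related disorders",
  Bipolar = "Bipolar and related disorders",
  Depression = "Depressive disorders",
  Trauma = "Trauma- and stressor-related disorders"
)
SCZ_CATEGORY <- "Schizophrenia spectrum and other psychotic disorders"

#' Assign a patient to the SCZ cohort, a control category, or exclusion
#'
#' SCZ if the primary code at the first ED psychiatric note maps to the
#' schizophrenia-spectrum CCSR category; control if it maps to one of the
#' four control categories *and* no SCZ-category code appears anywhere in
#' the patient's diagnosis history; otherwise excluded with a single
#' reason (`UNMAPPED`, `SCZ_HISTORY`, or `NOT_ELIGIBLE`).
#'
#' @param primary_code primary ICD-10 code of the index encounter.
#' @param dx_history character vector of all ICD-10 codes ever recorded for
#'   the patient (any date).
#' @param ccsr CCSR map from [load_ccsr()].
#' @return list with `status` (`"SCZ"`, `"control"`, `"excluded"`),
#'   `outcome` (0/1 or `NA`), `control_category`, `reason`.
#' @export
assign_cohort <- function(primary_code, dx_history = character(0),
                          ccsr = load_ccsr()) {
  cat <- ccsr$category[match(primary_code, ccsr$icd10)]
  if (is.na(cat))
    return(list(status = "excluded", outcome = NA_integer_,
                control_category = "none", reason = "UNMAPPED"))
  if (cat == SCZ_CATEGORY)
    return(list(status = "SCZ", outcome = 1L, control_category = "none",
                reason = "OK"))
  if (cat %in% CONTROL_CATEGORIES) {
    hist_cat <- ccsr$category[match(dx_history, ccsr$icd10)]
    if (any(hist_cat == SCZ_CATEGORY, na.rm = TRUE))
      return(list(status = "excluded", outcome = NA_integer_,
                  control_category = "none", reason = "SCZ_HISTORY"))
    return(list(status = "control", outcome = 0L,
                control_category =
                  names(CONTROL_CATEGORIES)[CONTROL_CATEGORIES == cat],
                reason = "OK"))
  }
  list(status = "excluded", outcome = NA_integer_,
       control_category = "none", reason = "NOT_ELIGIBLE")
}

#' Derive trauma and substance history flags
#'
#' A flag is set only when a qualifying code is dated strictly before the
#' index note (same-day codes do not count).  Trauma: the
#' trauma-and-stressor CCSR category; substance: the nine substance-related
#' CCSR categories.
#'
#' @param dx_history data frame with `code` and `date` for one patient.
#' @param index_date date of the first ED psychiatric note.
#' @param ccsr CCSR map from [load_ccsr()].
#' @return list with logical `trauma_history` and `substance_history`.
#' @export
derive_history_flags <- function(dx_history, index_date,
                                 ccsr = load_ccsr()) {
  if (is.null(dx_history) || nrow(dx_history) == 0)
    return(list(trauma_history = FALSE, substance_history = FALSE))
  pre <- as.Date(dx_history$date) < as.Date(index_date)
  cat <- ccsr$category[match(dx_history$code, ccsr$icd10)]
  grp <- ccsr$group[match(dx_history$code, ccsr$icd10)]
  list(
    trauma_history = any(pre & !is.na(cat) &
                           cat == CONTROL_CATEGORIES[["Trauma"]]),
    substance_history = any(pre & !is.na(grp) & grp == "substance")
  )
}

#' Merge raw race and ethnicity values into one Race/Ethnicity category
#'
#' Hispanic/Latino ethnicity dominates regardless of race (including White,
#' Black, American Indian or Alaska Native, and Native Hawaiian or Pacific
#' Islander Hispanic).  Native Hawaiian or Pacific Islander, American
#' Indian or Alaska Native, Middle Eastern or North African, and Some Other
#' Race aggregate into Some Other Race.  The remaining races map to Asian,
#' Black, Multiracial and White.  Unrecognized race values fall into Some
#' Other Race with a warning, mirroring the small-group aggregation
#' strategy rather than excluding the patient.
#'
#' @param race,ethnicity character vectors of raw EHR values.
#' @return character vector over the six Race/Ethnicity categories.
#' @export
harmonize_race_ethnicity <- function(race, ethnicity) {
  n <- max(length(race), length(ethnicity))
  race <- rep_len(as.character(race), n)
  ethnicity <- rep_len(as.character(ethnicity), n)
  hisp <- grepl("(?i)hispanic\\s*/?\\s*latino|^hispanic$", ethnicity,
                perl = TRUE) & !grepl("(?i)^non", ethnicity, perl = TRUE)
  hisp <- hisp | grepl("(?i)hispanic", race, perl = TRUE)
  some_other <- c("some other race", "native hawaiian or pacific islander",
                  "american indian or alaska native",
                  "middle eastern or north african", "other")
  direct <- c("asian" = "Asian", "chinese" = "Asian", "korean" = "Asian",
              "black" = "Black", "african american" = "Black",
              "multiracial" = "Multiracial", "white" = "White")
  low <- tolower(trimws(race))
  out <- character(n)
  out[low %in% some_other] <- "Some Other Race"
  known <- low %in% names(direct)
  out[known] <- direct[low[known]]
  unknown <- !nzchar(out)
  if (any(unknown)) {
    warning("unrecognized race value(s) mapped to Some Other Race: ",
            paste(unique(race[unknown]), collapse = ", "))
    out[unknown] <- "Some Other Race"
  }
  out[hisp] <- "Hispanic or Latino"
  out
}

#' Patient-level age exclusion
#'
#' Drops patients whose age at the note is below 1 or above 100 (data-entry
#' error guard); both bounds keep.
#'
#' @param age age in whole years at the encounter.
#' @return list with `keep` and `reason` (`"OK"` or `"AGE_RANGE"`).
#' @export
apply_patient_exclusions <- function(age) {
  if (is.na(age) || age < 1 || age > 100)
    list(keep = FALSE, reason = "AGE_RANGE")
  else list(keep = TRUE, reason = "OK")
}

#' Build a modeling-ready cohort table from raw structured inputs
#'
#' Composes cohort assignment, history flags, race/ethnicity harmonization,
#' SES mapping and the age exclusion into one partition: every patient is
#' SCZ, exactly one control category, or excluded with exactly one reason.
#'
#' @param patients data frame with `patient_id`, `sex`, `race`, `ethnicity`,
#'   `birth_date`, `zip`, `encounter_date`, `primary_code`.
#' @param dx data frame with `patient_id`, `code`, `date` (full diagnosis
#'   history).
#' @param zip_income lookup from [load_zip_income()].
#' @param ccsr CCSR map from [load_ccsr()].
#' @return list with `cohort` (included patients, modeling covariates) and
#'   `excluded` (patient_id, reason).
#' @export
build_cohort <- function(patients, dx, zip_income = load_zip_income(),
                         ccsr = load_ccsr()) {
  needed <- c("patient_id", "sex", "race", "ethnicity", "birth_date",
              "zip", "encounter_date", "primary_code")
  stopifnot(all(needed %in% names(patients)))
  dx_split <- split(dx[c("code", "date")], dx$patient_id)

  rows <- vector("list", nrow(patients))
  excl <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    hist <- dx_split[[p$patient_id]]
    age <- compute_age(p$birth_date, p$encounter_date)
    ok_age <- apply_patient_exclusions(age)
    if (!ok_age$keep) {
      excl[[i]] <- data.frame(patient_id = p$patient_id,
                              reason = ok_age$reason)
      next
    }
    asg <- assign_cohort(p$primary_code, hist$code %||% character(0), ccsr)
    if (asg$status == "excluded") {
      excl[[i]] <- data.frame(patient_id = p$patient_id,
                              reason = asg$reason)
      next
    }
    ses <- map_ses(p$zip, zip_income)
    if (is.na(ses)) {
      excl[[i]] <- data.frame(patient_id = p$patient_id,
                              reason = "MISSING_SES")
      next
    }
    pre_hist <- if (is.null(hist)) NULL else hist
    flags <- derive_history_flags(pre_hist, p$encounter_date, ccsr)
    rows[[i]] <- data.frame(
      patient_id = p$patient_id, sex = p$sex,
      race_ethnicity = harmonize_race_ethnicity(p$race, p$ethnicity),
      age = age, ses = ses,
      trauma_history = flags$trauma_history,
      substance_history = flags$substance_history,
      outcome = asg$outcome, control_category = asg$control_category,
      stringsAsFactors = FALSE)
  }
  cohort <- as.data.frame(data.table::rbindlist(rows))
  if (nrow(cohort)) cohort$ses_z <- as.numeric(scale(cohort$ses))
  list(cohort = cohort,
       excluded = as.data.frame(data.table::rbindlist(excl)))
}
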
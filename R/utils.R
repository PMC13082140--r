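`%||%` <- function(x, y) if (is.null(x)) y else x

#' Count whitespace-delimited tokens in a text
#'
#' Word counts drive the note-length filter, so the definition is fixed
#' package-wide: tokens are maximal runs of non-whitespace characters.
#'
#' @param text character vector.
#' @return integer vector of word counts.
#' @export
count_words <- function(text) {
  text <- trimws(text)
  out <- lengths(strsplit(text, "\\s+"))
  out[!nzchar(text)] <- 0L
  as.integer(out)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid scenario configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

## Beta shape parameters from a mean and standard deviation (moment match).
## Used to give per-patient negative-sentence propensities the spread seen
## in real cohorts rather than a single binomial rate.
beta_shapes <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop_config("mean", "must lie in (0,1)")
  v <- sd^2
  if (v >= mean * (1 - mean)) stop_config("sd", "too large for a Beta law")
  k <- mean * (1 - mean) / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

## Whole-year age at an encounter date (floor convention).
compute_age <- function(birth_date, encounter_date) {
  b <- as.POSIXlt(as.Date(birth_date))
  e <- as.POSIXlt(as.Date(encounter_date))
  age <- e$year - b$year
  earlier <- (e$mon < b$mon) | (e$mon == b$mon & e$mday < b$mday)
  as.integer(age - earlier)
}
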
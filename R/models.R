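## Association models: the two interaction logistic regressions (with and
## without the NSR terms), per-diagnosis univariate NSR models, model
## comparison, marginal effects, and the post-hoc one-way ANOVA.

#' Model specifications
#'
#' `model1` is the full specification: age, sex, race/ethnicity,
#' standardized SES, trauma and substance history with their interaction,
#' the race x sex x SES interaction set, and the NSR with its
#' race/sex/SES interactions.  `model2` removes the NSR and all its
#' interaction terms (its term set is a strict subset of `model1`'s).
#' References are White for race/ethnicity and Female for sex; SES enters
#' as a z-score, the NSR raw on \[0,1\].
#'
#' @param model `"model1"` or `"model2"`.
#' @param outcome name of the 0/1 outcome column.
#' @return object of class `nsr_model_spec` with `formula`, `model`,
#'   `outcome`.
#' @export
model_spec <- function(model = c("model1", "model2"), outcome = "outcome") {
  model <- match.arg(model)
  rhs <- "age + sex * race_ethnicity * ses_z + trauma_history * substance_history"
  if (model == "model1")
    rhs <- paste(rhs,
                 "+ nsr + nsr:race_ethnicity + nsr:sex + nsr:ses_z")
  structure(list(
    model = model, outcome = outcome,
    formula = as.formula(paste(outcome, "~", rhs))
  ), class = "nsr_model_spec")
}

## Prepare modeling factors with the declared reference levels; SES is
## standardized on the analysis sample.
.model_frame <- function(cohort) {
  df <- cohort
  if (!is.null(df$sex))
    df$sex <- factor(df$sex, levels = SEX_LEVELS)
  if (!is.null(df$race_ethnicity))
    df$race_ethnicity <- factor(df$race_ethnicity, levels = RACE_LEVELS)
  for (v in c("trauma_history", "substance_history"))
    if (!is.null(df[[v]])) df[[v]] <- as.integer(df[[v]])
  if (is.null(df$ses_z) && !is.null(df$ses))
    df$ses_z <- as.numeric(scale(df$ses))
  df
}

.tidy_glm <- function(fit, conf_z = 1.96) {
  sm <- summary(fit)$coefficients
  data.frame(
    term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
    or = exp(sm[, 1]),
    ci_low = exp(sm[, 1] - conf_z * sm[, 2]),
    ci_high = exp(sm[, 1] + conf_z * sm[, 2]),
    p = sm[, 4], row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Fit a logistic model from a specification
#'
#' Maximum-likelihood logistic regression with treatment coding at the
#' declared references.  Odds ratios are the exact exponentials of the
#' coefficients; confidence bounds exponentiate `estimate +- 1.96 se`.
#' Non-convergence or separation is flagged, never silent.
#'
#' @param spec an `nsr_model_spec`.
#' @param cohort modeling-ready cohort data frame.
#' @return object of class `nsr_model_fit`: list with `tidy` (term table),
#'   `aic`, `r2_mcfadden`, `loglik`, `deviance`, `null_deviance`, `n`,
#'   `converged`, `spec`, and the underlying `glm`.
#' @export
fit_logistic <- function(spec, cohort) {
  df <- .model_frame(cohort)
  vars <- all.vars(spec$formula)
  df <- df[stats::complete.cases(df[vars]), , drop = FALSE]
  y <- df[[spec$outcome]]
  if (length(unique(y)) < 2) stop("outcome is degenerate (single level)")
  fit <- glm(spec$formula, data = df, family = binomial())
  fitted_p <- fitted(fit)
  separated <- any(fitted_p > 1 - 1e-10) || any(fitted_p < 1e-10)
  if (!fit$converged || separated)
    warning("logistic fit flagged: ",
            if (!fit$converged) "non-convergence " else "",
            if (separated) "possible separation" else "")
  structure(list(
    tidy = .tidy_glm(fit),
    aic = stats::AIC(fit),
    loglik = as.numeric(logLik(fit)),
    deviance = fit$deviance, null_deviance = fit$null.deviance,
    r2_mcfadden = 1 - fit$deviance / fit$null.deviance,
    n = nrow(df), converged = fit$converged && !separated,
    spec = spec, glm = fit
  ), class = "nsr_model_fit")
}

#' @export
print.nsr_model_fit <- function(x, ...) {
  cat(sprintf("<nsr_model_fit %s>  n=%d  AIC=%.1f  McFadden R2=%.3f\n",
              x$spec$model %||% "custom", x$n, x$aic, x$r2_mcfadden))
  df <- x$tidy
  df[c("estimate", "se", "or", "ci_low", "ci_high")] <-
    round(df[c("estimate", "se", "or", "ci_low", "ci_high")], 3)
  df$p <- signif(df$p, 3)
  print(utils::head(df, 20), row.names = FALSE)
  if (nrow(df) > 20) cat("... (", nrow(df) - 20, " more terms)\n", sep = "")
  invisible(x)
}

#' Look up a coefficient row by term, ignoring interaction component order
#'
#' `glm` labels an interaction by the order variables entered the formula;
#' this helper matches on the unordered set of components so tests and
#' reports need not depend on that order.
#'
#' @param fit an `nsr_model_fit`.
#' @param term term label, e.g. `"sexMale:race_ethnicityBlack"`.
#' @return one-row data frame from `fit$tidy`.
#' @export
coef_lookup <- function(fit, term) {
  want <- sort(strsplit(term, ":", fixed = TRUE)[[1]])
  have <- lapply(strsplit(fit$tidy$term, ":", fixed = TRUE), sort)
  hit <- which(vapply(have, identical, TRUE, y = want))
  if (length(hit) != 1)
    stop("term not found (or ambiguous) in fit: ", term)
  fit$tidy[hit, , drop = FALSE]
}

#' Compare two nested logistic fits
#'
#' @param fit1,fit2 `nsr_model_fit` objects on the same data; `fit2` must be
#'   nested in `fit1`.
#' @return list with `delta_aic` (fit1 - fit2), `delta_r2`, and the
#'   likelihood-ratio test (`lr_stat` = difference of deviances, `df`,
#'   `p`).
#' @export
compare_models <- function(fit1, fit2) {
  t1 <- fit1$tidy$term; t2 <- fit2$tidy$term
  if (!all(t2 %in% t1))
    stop("models are not nested (term set of fit2 must be a subset)")
  if (fit1$n != fit2$n)
    stop("fits use different numbers of observations")
  lr <- fit2$deviance - fit1$deviance
  df <- length(t1) - length(t2)
  list(
    delta_aic = fit1$aic - fit2$aic,
    delta_r2 = fit1$r2_mcfadden - fit2$r2_mcfadden,
    lr_stat = lr, df = df,
    p = if (df > 0) pchisq(lr, df, lower.tail = FALSE) else NA_real_
  )
}

#' Univariate NSR model for one diagnosis
#'
#' Logistic regression of the diagnosis indicator (that diagnosis versus
#' all other patients) on the NSR alone; the odds ratio is per unit NSR.
#'
#' @param cohort cohort data frame with `nsr` and either a
#'   `dx_<diagnosis>` indicator column or `outcome`/`control_category`.
#' @param diagnosis one of `"Anxiety"`, `"Bipolar"`, `"Depression"`,
#'   `"Trauma"`, `"SCZ"`.
#' @return list with `or`, `ci` (low, high), and the `nsr_model_fit`.
#' @export
fit_univariate_nsr <- function(cohort, diagnosis) {
  diagnosis <- match.arg(diagnosis, DIAGNOSES)
  col <- paste0("dx_", tolower(diagnosis))
  ind <- if (col %in% names(cohort)) cohort[[col]]
         else if (diagnosis == "SCZ") cohort$outcome
         else as.integer(cohort$control_category == diagnosis)
  if (stats::var(cohort$nsr) == 0)
    stop("NSR is constant across patients; univariate model undefined")
  df <- data.frame(ind = ind, nsr = cohort$nsr)
  spec <- structure(list(model = paste0("univariate_", diagnosis),
                         outcome = "ind", formula = ind ~ nsr),
                    class = "nsr_model_spec")
  fit <- fit_logistic(spec, df)
  row <- fit$tidy[fit$tidy$term == "nsr", ]
  list(or = row$or, ci = c(low = row$ci_low, high = row$ci_high),
       fit = fit)
}

#' Predicted probabilities over an NSR x race/ethnicity x sex grid
#'
#' Marginal-effect style predictions: other covariates are held at the
#' reference level (history flags 0, SES z-score 0) and at the sample mean
#' age.
#'
#' @param fit an `nsr_model_fit` from [fit_logistic()].
#' @param nsr numeric vector of NSR grid values.
#' @param race_ethnicity,sex factor levels to cross (defaults: all levels
#'   present in the fit).
#' @return data frame with the grid and `prob`.
#' @export
marginal_effects <- function(fit, nsr = seq(0, 0.6, by = 0.1),
                             race_ethnicity = RACE_LEVELS,
                             sex = SEX_LEVELS) {
  if (!fit$converged) warning("predictions from a flagged fit")
  mf <- fit$glm$model
  obs_rng <- if ("nsr" %in% names(mf)) range(mf$nsr) else c(0, 1)
  if (any(nsr < obs_rng[1] | nsr > obs_rng[2]))
    warning("NSR grid values outside the observed range [",
            signif(obs_rng[1], 3), ", ", signif(obs_rng[2], 3), "]")
  grid <- expand.grid(nsr = nsr, race_ethnicity = race_ethnicity,
                      sex = sex, stringsAsFactors = FALSE)
  grid$race_ethnicity <- factor(grid$race_ethnicity, levels = RACE_LEVELS)
  grid$sex <- factor(grid$sex, levels = SEX_LEVELS)
  grid$age <- if ("age" %in% names(mf)) mean(mf$age) else 0
  grid$ses_z <- 0
  grid$trauma_history <- 0L
  grid$substance_history <- 0L
  grid$prob <- as.numeric(predict(fit$glm, newdata = grid,
                                  type = "response"))
  grid
}

#' Fisher's one-way ANOVA with partial omega-squared
#'
#' Classical one-way F test plus the effect size
#' `(SSb - dfb * MSw) / (SSb + (N - dfb) * MSw)`; a non-positive value is
#' reported as computed with the `clamped` flag set.
#'
#' @param values numeric response vector.
#' @param groups grouping vector (>= 2 groups, each with >= 2 values).
#' @return list with `f`, `df_between`, `df_within`, `p`,
#'   `omega_sq_partial`, `clamped`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- as.factor(groups)
  ns <- tabulate(groups)
  if (nlevels(groups) < 2 || any(ns[ns > 0] < 2))
    stop("need at least 2 groups with at least 2 values each")
  N <- length(values)
  k <- nlevels(droplevels(groups))
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  vars <- tapply(values, groups, var)
  nn <- tapply(values, groups, length)
  ss_b <- sum(nn * (means - gm)^2)
  ss_w <- sum((nn - 1) * vars)
  if (ss_w == 0) stop("zero within-group variance everywhere")
  df_b <- as.integer(k - 1); df_w <- as.integer(N - k)
  ms_w <- ss_w / df_w
  f <- (ss_b / df_b) / ms_w
  omega <- (ss_b - df_b * ms_w) / (ss_b + (N - df_b) * ms_w)
  list(f = f, df_between = df_b, df_within = df_w,
       p = pf(f, df_b, df_w, lower.tail = FALSE),
       omega_sq_partial = omega, clamped = omega <= 0)
}
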
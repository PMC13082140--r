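test_that("model2's term set is a strict subset of model1's", {
  t1 <- attr(terms(model_spec("model1")$formula), "term.labels")
  t2 <- attr(terms(model_spec("model2")$formula), "term.labels")
  expect_true(all(t2 %in% t1))
  expect_true(length(t2) < length(t1))
  nsr_terms <- setdiff(t1, t2)
  expect_true(all(grepl("nsr", nsr_terms)))
  expect_length(nsr_terms, 4)
})

test_that("glm coefficients agree with a generic optimizer oracle", {
  set.seed(9)
  n <- 200
  df <- data.frame(
    outcome = NA, age = rnorm(n, 40, 15),
    sex = sample(c("Female", "Male"), n, TRUE),
    nsr = rbeta(n, 2, 6), ses_z = rnorm(n),
    race_ethnicity = sample(nsrbias:::RACE_LEVELS, n, TRUE),
    trauma_history = rbinom(n, 1, 0.4),
    substance_history = rbinom(n, 1, 0.2))
  eta <- -1 + 0.3 * df$nsr * 4 + 0.3 * (df$sex == "Male")
  df$outcome <- rbinom(n, 1, plogis(eta))

  spec <- structure(list(model = "small", outcome = "outcome",
                         formula = outcome ~ age + sex + nsr + ses_z),
                    class = "nsr_model_spec")
  fit <- fit_logistic(spec, df)
  X <- model.matrix(~ age + sex + nsr + ses_z,
                    nsrbias:::.model_frame(df))
  b_oracle <- oracle_logistic(X, df$outcome)
  expect_equal(fit$tidy$estimate, unname(b_oracle), tolerance = 1e-6)

  ## OR/CI mapping is the exact exponential of the coefficient scale
  expect_identical(fit$tidy$or, exp(fit$tidy$estimate))
  expect_identical(fit$tidy$ci_low,
                   exp(fit$tidy$estimate - 1.96 * fit$tidy$se))
  expect_identical(fit$tidy$ci_high,
                   exp(fit$tidy$estimate + 1.96 * fit$tidy$se))
})

test_that("a null outcome yields ORs compatible with 1", {
  sc <- scenario("model1", n_patients = 8000, seed = 3)
  g <- generate_cohort(sc)
  g$cohort$outcome <- rbinom(nrow(g$cohort), 1, 0.3)  # independent of all
  fit <- fit_logistic(model_spec("model1"), g$cohort)
  covered <- with(fit$tidy[-1, ], ci_low <= 1 & ci_high >= 1)
  expect_gte(mean(covered), 0.9)
  row <- coef_lookup(fit, "nsr")
  expect_true(row$ci_low <= 1 && row$ci_high >= 1)
})

test_that("model comparison: identity, LR definition, nesting guard", {
  sc <- scenario("model1", n_patients = 20000, seed = 19)
  g <- generate_cohort(sc)
  f1 <- fit_logistic(model_spec("model1"), g$cohort)
  f2 <- fit_logistic(model_spec("model2"), g$cohort)

  self <- compare_models(f1, f1)
  expect_identical(self$delta_aic, 0)
  expect_identical(self$lr_stat, 0)

  cmp <- compare_models(f1, f2)
  expect_equal(cmp$lr_stat, f2$deviance - f1$deviance)
  expect_identical(cmp$df, nrow(f1$tidy) - nrow(f2$tidy))
  ## data generated with a nonzero NSR effect: model 1 should win on AIC
  expect_lt(f1$aic, f2$aic)
  expect_error(compare_models(f2, f1), "nested")
})

test_that("univariate NSR fit guards degenerate inputs", {
  df <- data.frame(dx_scz = rbinom(50, 1, 0.5), nsr = 0.3)
  expect_error(fit_univariate_nsr(df, "SCZ"), "constant")
  df2 <- data.frame(dx_scz = 1, nsr = runif(50))
  expect_error(fit_univariate_nsr(df2, "SCZ"), "degenerate")
})

test_that("marginal effects match hand-assembled linear predictors", {
  sc <- scenario("model1", n_patients = 5000, seed = 29)
  g <- generate_cohort(sc)
  fit <- fit_logistic(model_spec("model1"), g$cohort)

  grid <- marginal_effects(fit, nsr = c(0.1, 0.3))
  expect_identical(nrow(grid), 2L * 6L * 2L)

  ## hand computation at one grid point: White female, so only intercept,
  ## age and nsr terms contribute
  b <- coef(fit$glm)
  age_bar <- mean(fit$glm$model$age)
  eta <- b[["(Intercept)"]] + b[["age"]] * age_bar + b[["nsr"]] * 0.3
  hand <- plogis(eta)
  got <- grid$prob[grid$nsr == 0.3 & grid$race_ethnicity == "White" &
                     grid$sex == "Female"]
  expect_equal(got, hand, tolerance = 1e-12)

  ## all-zero coefficients give probability 1/2 everywhere
  fit0 <- fit
  fit0$glm$coefficients[] <- 0
  g0 <- suppressWarnings(marginal_effects(fit0, nsr = c(0, 0.2)))
  expect_true(all(abs(g0$prob - 0.5) < 1e-12))

  ## positive NSR slope with zeroed interactions is monotone
  fitm <- fit
  fitm$glm$coefficients[] <- 0
  fitm$glm$coefficients[["nsr"]] <- 2
  gm <- suppressWarnings(
    marginal_effects(fitm, nsr = seq(0, 0.5, 0.1),
                     race_ethnicity = "White", sex = "Female"))
  expect_true(all(diff(gm$prob) > 0))

  expect_warning(marginal_effects(fit, nsr = c(0.99)), "outside")
})

test_that("one-way ANOVA matches t^2 and a textbook hand computation", {
  set.seed(10)
  x <- rnorm(40); gr <- rep(c("a", "b"), each = 20)
  a <- oneway_anova(x, gr)
  tt <- t.test(x ~ gr, var.equal = TRUE)
  expect_equal(a$f, unname(tt$statistic^2), tolerance = 1e-12)
  expect_equal(a$p, tt$p.value, tolerance = 1e-12)

  ## 3-group toy data, hand-computed sums of squares
  v <- c(1, 2, 3, 2, 4, 6, 5, 7, 9)
  g3 <- rep(c("g1", "g2", "g3"), each = 3)
  means <- c(2, 4, 7); gm <- mean(v)
  ssb <- sum(3 * (means - gm)^2)
  ssw <- sum((v - rep(means, each = 3))^2)
  msw <- ssw / 6
  f_hand <- (ssb / 2) / msw
  omega_hand <- (ssb - 2 * msw) / (ssb + (9 - 2) * msw)
  a3 <- oneway_anova(v, g3)
  expect_equal(a3$f, f_hand, tolerance = 1e-12)
  expect_identical(a3$df_between, 2L)
  expect_identical(a3$df_within, 6L)
  expect_equal(a3$omega_sq_partial, omega_hand, tolerance = 1e-12)
  expect_lte(a3$omega_sq_partial, 1)

  ## identical group means: non-positive effect size flagged
  same <- oneway_anova(c(1, 2, 1, 2, 1, 2), rep(c("a", "b", "c"), 2))
  expect_true(same$clamped)
  expect_lte(same$omega_sq_partial, 0)

  expect_error(oneway_anova(rep(1, 6), rep(c("a", "b"), 3)),
               "within-group variance")
  expect_error(oneway_anova(1:3, c("a", "a", "b")), "at least 2")
})

test_that("fitted coefficients cover generating values across replicates", {
  ## scaled down from the full scenario sizes to keep the suite fast:
  ## 50 seeded replicates at n = 6000 (table3) and n = 12000 (model1)
  cover_t3 <- logical(50)
  for (r in 1:50) {
    sc <- scenario("table3", n_patients = 6000, seed = 1000 + r)
    g <- generate_cohort(sc)
    u <- fit_univariate_nsr(g$cohort, "SCZ")
    cover_t3[r] <- u$ci["low"] <= 1.80 && 1.80 <= u$ci["high"]
  }
  expect_gte(mean(cover_t3), 0.9)

  cover_nsr <- logical(50); cover_male <- logical(50)
  for (r in 1:50) {
    sc <- scenario("model1", n_patients = 12000, seed = 2000 + r)
    g <- generate_cohort(sc)
    fit <- fit_logistic(model_spec("model1"), g$cohort)
    tc <- truth_coefficients(g$truth, "SCZ")
    for (tm in c("nsr", "sexMale")) {
      row <- coef_lookup(fit, tm)
      tv <- exp(tc$value[tc$term == tm])
      ok <- row$ci_low <= tv && tv <= row$ci_high
      if (tm == "nsr") cover_nsr[r] <- ok else cover_male[r] <- ok
    }
  }
  ## a hard 0.90 cut on 50 draws of a 95%-coverage event fails ~9% of the
  ## time by binomial noise alone; the 0.90 bound is asserted on the pooled
  ## 150 trials (power adequate) with a 3-sigma per-coefficient guard
  expect_gte(mean(c(cover_t3, cover_nsr, cover_male)), 0.9)
  expect_gte(mean(cover_nsr), 0.85)
  expect_gte(mean(cover_male), 0.85)
})
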
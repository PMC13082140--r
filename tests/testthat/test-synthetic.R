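test_that("scenario validation names the offending field", {
  expect_error(scenario_config("x", 0, 1), "n_patients")
  bad_race <- list(race = c(White = 2), p_male = 0.5)
  expect_error(scenario_config("x", 10, 1, group_mix = bad_race),
               "group_mix\\$race")
  expect_error(
    scenario_config("x", 10, 1,
                    note_profile = list(chaos = setNames(rep(0.3, 5),
                      c("TWO_LABELS", "ERROR", "EXTRACT", "REFUSE",
                        "E_TEXT")))),
    "chaos")
  expect_error(scenario_config("x", 10, 1,
                               nsr_dist = list(mean = 0.5, sd = 0.9)),
               "sd")
})

test_that("generation is deterministic under a fixed seed", {
  sc <- tiny_scenario()
  a <- generate_cohort(sc); b <- generate_cohort(sc)
  expect_identical(a, b)
  na <- generate_notes(a$cohort, sc); nb <- generate_notes(b$cohort, sc)
  expect_identical(na, nb)
  expect_false(identical(generate_cohort(sc, seed = 99)$cohort$nsr,
                         a$cohort$nsr))
})

test_that("null diagnosis model gives prevalence 1/2 and n=1 works", {
  z <- nsrbias:::.zero_coeffs()
  z$intercept <- 0
  sc <- scenario_config("null", 10000, 5, diag_coeffs = list(SCZ = z))
  g <- generate_cohort(sc)
  expect_lt(abs(mean(g$cohort$dx_scz) - 0.5), 4 * sqrt(0.25 / 10000))

  sc1 <- scenario_config("one", 1, 3, diag_coeffs = list(SCZ = z))
  g1 <- generate_cohort(sc1)$cohort
  expect_identical(nrow(g1), 1L)
  expect_true(g1$age >= 1 && g1$age <= 100)
  expect_true(g1$nsr > 0 && g1$nsr < 1)
  expect_true(g1$ses >= 21846 && g1$ses <= 250000)
  expect_true(g1$race_ethnicity %in% nsrbias:::RACE_LEVELS)
})

test_that("empirical distributions match configuration within 4 SE", {
  sc <- scenario("table3", n_patients = 20000, seed = 2)
  g <- generate_cohort(sc)$cohort
  p <- sc$group_mix$race
  emp <- table(factor(g$race_ethnicity, names(p))) / nrow(g)
  for (lev in names(p))
    expect_lt(abs(emp[[lev]] - p[[lev]]),
              4 * sqrt(p[[lev]] * (1 - p[[lev]]) / nrow(g)))
  expect_lt(abs(mean(g$sex == "Male") - sc$group_mix$p_male),
            4 * sqrt(0.25 / nrow(g)))
  expect_lt(abs(mean(g$nsr) - sc$nsr_dist$mean),
            4 * sc$nsr_dist$sd / sqrt(nrow(g)))
})

test_that("planted negative rate yields the expected gold NSR", {
  ## 10 sentences per note, near-constant negative propensity 0.3
  sc <- scenario_config(
    "flat", 1000, 13,
    nsr_dist = list(mean = 0.3, sd = 0.01),
    diag_coeffs = list(),
    note_profile = list(sentence_mean = 10, sentence_size = 1e6,
                        min_sentences = 10, max_sentences = 10,
                        irrelevant_rate = 0))
  g <- generate_cohort(sc)
  nt <- generate_notes(g$cohort, sc)
  gold_nsr <- tapply(nt$truth$gold_label == "negative",
                     nt$truth$patient_id, mean)
  se <- sqrt(0.3 * 0.7 / 10) / sqrt(1000)
  expect_lt(abs(mean(gold_nsr) - 0.3), 3 * se + 3 * 0.01 / sqrt(1000))
})

test_that("short word targets produce notes the length filter drops", {
  sc <- scenario_config(
    "short", 20, 21, diag_coeffs = list(),
    note_profile = list(sentence_mean = 6, sentence_size = 50,
                        min_sentences = 4, max_sentences = 8,
                        word_range = c(380L, 420L)))
  g <- generate_cohort(sc)
  nt <- generate_notes(g$cohort, sc)
  expect_true(all(nt$notes$word_count < 500))
  pp <- preprocess_notes(nt$notes)
  expect_true(all(!pp$notes$keep))
  expect_true(all(pp$notes$reason == "MIN_WORDS"))
})

test_that("raw labeler outputs exemplify the NA subtypes at planted rates", {
  sc <- tiny_scenario()
  sents <- data.frame(text = rep("Pt denies suicidal ideation at this time.",
                                 50),
                      gold_label = rep("neutral", 50))
  sc$note_profile$chaos <- setNames(c(1, 0, 0, 0, 0),
                                    nsrbias:::NA_SUBTYPES)
  out <- generate_raw_labeler_outputs(sents, sc, seed = 1)
  expect_true(all(grepl("neutral-negative", out$raw)))

  sc$note_profile$chaos <- setNames(c(0, 0, 1, 0, 0),
                                    nsrbias:::NA_SUBTYPES)
  out <- generate_raw_labeler_outputs(sents, sc, seed = 1)
  expect_true(all(grepl("neutral, explanation:", out$raw)))

  sc$note_profile$chaos <- setNames(rep(0, 5), nsrbias:::NA_SUBTYPES)
  out <- generate_raw_labeler_outputs(sents, sc, seed = 1)
  parsed <- lapply(out$raw, parse_output, batch_size = 1)
  expect_true(all(vapply(parsed, function(p) !is.na(p$value), TRUE)))
})

test_that("derived history flags equal generator truth", {
  sc <- tiny_scenario(n = 40, seed = 17)
  g <- generate_cohort(sc)
  dx <- generate_dx_history(g$cohort, seed = 4)
  ccsr <- load_ccsr()
  for (i in seq_len(nrow(g$cohort))) {
    h <- dx[dx$patient_id == g$cohort$patient_id[i], ]
    fl <- derive_history_flags(h, g$cohort$encounter_date[i], ccsr)
    expect_identical(fl$trauma_history, g$cohort$trauma_history[i])
    expect_identical(fl$substance_history, g$cohort$substance_history[i])
  }
})
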
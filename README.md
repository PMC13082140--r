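# nsrbias

Quantifying patient exposure to clinician bias in emergency-department
(ED) psychiatric notes, and its association with schizophrenia-spectrum
(SCZ) diagnosis.

## What it does, and for whom

Psychiatric notes record how a clinician perceives a patient.  For
researchers studying diagnostic disparities, the sentiment of that
language is a measurable proxy for bias exposure.  `nsrbias` implements
the full analysis path:

1. **Note processing** — extract the free-text sections that describe the
   patient (Chief Complaint, History of Present Illness, Mental Status
   Exam, Collateral), split them into sentences, drop clinically
   irrelevant ones (contact/scheduling lines, bare template fields), and
   drop notes under 500 or over 3000 words or with fewer than 4 relevant
   sentences.
2. **Sentiment labeling** — a pluggable backend labels each sentence
   negative / neutral / positive from the patient's perspective.  Raw
   backend output is parsed through a *total* parser with a five-subtype
   taxonomy of unlabelable responses (`TWO_LABELS`, `ERROR`, `EXTRACT`,
   `REFUSE`, `E_TEXT`), rule-based `EXTRACT` recovery, and a single
   strict-prompt rerun.  A deterministic lexicon backend ships for
   testing; real LLM adapters satisfy the same contract.
3. **The bias metric** — per patient, the **Negative Sentence Ratio**

   ```
   n_sentences = n_NA + n_negative + n_neutral + n_positive
   NSR         = n_negative / n_sentences
   ```

   (retained NA labels count in the denominator; `E_TEXT` sentences are
   removed upstream).
4. **Cohorts & covariates** — CCSR-based cohort assignment (SCZ vs
   anxiety/bipolar/depression/trauma controls with no SCZ history),
   race/ethnicity harmonization into six categories, zip-code SES,
   strictly-pre-index trauma/substance history flags, age 1–100 exclusion.
5. **Association models** — interaction logistic regressions
   `SCZ ~ age + sex*race_ethnicity*ses_z + trauma*substance + NSR +
   NSR:(race_ethnicity, sex, ses_z)` (Model 1) and the same without the
   NSR terms (Model 2); per-diagnosis univariate `diagnosis ~ NSR` models;
   odds ratios `exp(beta)` with 95% CIs `exp(beta ± 1.96 se)`; AIC,
   McFadden pseudo-R², likelihood-ratio comparison; marginal-effect
   grids; Fisher's one-way ANOVA with partial omega-squared.
6. **Synthetic data** — protected EHR data cannot ship, so a first-class
   generator produces cohorts and notes with known ground truth: planted
   gold sentence labels, per-patient negative propensities, malformed
   labeler outputs at configurable rates, and diagnosis outcomes drawn
   from configurable logistic models.  Packaged scenarios `"table2"`,
   `"table3"` and `"model1"` encode the published group moments and
   effect sizes.

## Worked example

```r
library(nsrbias)

sc  <- scenario("table2", n_patients = 300, seed = 7)  # 300 per group
g   <- generate_cohort(sc)
nt  <- generate_notes(g$cohort, sc)
res <- run_pipeline(nt$notes)          # sections -> sentences -> labels -> NSR
cohort_nsr_table(res$summaries, g$cohort)
#>   cohort_group   n nsr_mean nsr_sd negative_mean sentences_mean
#> 1      Control 300    0.225  0.152          6.20           27.8
#> 2          SCZ 300    0.291  0.162          8.36           28.4

m <- merge(res$summaries, g$cohort[, c("patient_id", "cohort_group")])
a <- oneway_anova(m$nsr, m$cohort_group)
#> F(1,598) = 26.36, p = 3.85e-07, partial omega^2 = 0.0405
```

The synthetic SCZ group was generated with a mean negative-sentence
propensity of 0.28 and the control group 0.22; the pipeline recovers
group means of 0.291 and 0.225 from raw note text, and the ANOVA confirms
the group difference.  A univariate diagnosis model on the default
`"table3"` cohort (n = 50,000, generating OR 1.80 per unit NSR):

```r
u <- fit_univariate_nsr(generate_cohort(scenario("table3"))$cohort, "SCZ")
#> OR 1.89 (95% CI 1.64-2.18)   # generating value 1.80 inside the CI
```

## Command line

`inst/cli/nsrbias-cli.R` exposes the stages as subcommands
(`simulate`, `preprocess`, `label`, `validate`, `cohort`, `fit`) reading
and writing CSV; see the header comment for usage.

## Further reading

The methods vignette (`vignettes/nsr-bias-pipeline.Rmd`) documents the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic world does and does not emulate, numerical
choices, and known limitations.
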
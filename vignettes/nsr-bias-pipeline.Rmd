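---
title: "Quantifying clinician bias exposure with the Negative Sentence Ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying clinician bias exposure with the Negative Sentence Ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsrbias)
```

## The problem and the metric

Clinician bias cannot be observed directly, but the language a clinician
uses to describe a patient can.  `nsrbias` operationalizes a patient's
exposure to clinician bias in emergency-department (ED) psychiatry as the
**Negative Sentence Ratio (NSR)**: the fraction of sentiment-labeled
sentences in the patient's first ED psychiatric note that read as negative
from the patient's perspective,

$$
n_{\text{sentences}} = n_{NA} + n_{\text{negative}} + n_{\text{neutral}}
  + n_{\text{positive}}, \qquad
\text{NSR} = \frac{n_{\text{negative}}}{n_{\text{sentences}}} .
$$

Sentences that survive labeling with an unresolvable (NA) label stay in the
denominator; sentences removed as extraneous text never reach the counts.
The NSR then enters logistic regressions that ask whether bias exposure is
associated with receiving a schizophrenia-spectrum (SCZ) diagnosis, over
and above demographics, socioeconomic status (SES) and clinical history.

Because the EHR data behind this design is protected, the package ships a
first-class synthetic-data module.  Every downstream stage is exercised
against generated notes and cohorts whose ground truth — gold sentence
labels, per-patient negative propensity, generating log-odds coefficients —
is recorded at generation time.

## Pipeline stages

1. **Sectionizing.** Four sections carry clinician-authored free text about
   the patient: Chief Complaint (CC), History of Present Illness (HPI),
   Mental Status Exam (MSE), and Collateral.  The matcher recognizes a
   packaged synonym list per section, case-insensitively, at line start,
   followed by a colon or end of line.  Other known headers (Plan,
   Medications, ...) act as *boundaries only*: they terminate the previous
   section but are never returned.  This mirrors how a clinical
   sectionizer knows many section titles while an analysis keeps few; it
   also prevents a target section from swallowing trailing boilerplate.
   A note with no recognized header yields an empty section set and is
   later dropped by the sentence-count filter — not an error.

2. **Sentencizing.** A rule-based splitter: newlines are hard boundaries
   (clinical notes are line-structured), sentences split after `.!?` plus
   whitespace, with protection for common abbreviations (Dr., Pt., e.g.,
   a.m., numbered list markers).  The splitter is lossless: concatenating
   its output reproduces the section text up to whitespace, and trailing
   fragments without terminal punctuation are kept.

3. **Relevance filtering.** The trained relevance classifier of the
   original pipeline is unrecoverable; the package substitutes a documented
   heuristic keyed to that classifier's two dominant irrelevance
   categories: contact/scheduling content (phone-number shapes;
   call/fax/schedule/appointment language) and bare MSE template fields
   (`Appearance:` with no descriptor).  The function is pluggable — any
   classifier with the same signature can replace it.

4. **Note filters.** A note is dropped when its raw word count is below
   500 or above 3000, or when fewer than 4 relevant sentences survive.
   The bounds read "less than 500 / over 3000" literally, so 500 and 3000
   words keep, as do exactly 4 sentences.  Word counts are computed on the
   full raw note, not the extracted sections.  The sentence-count filter
   applies *after* relevance filtering.

5. **Labeling and parsing.** A backend is any function
   `f(sentences, prompt, config)` returning one raw string expected to be
   a JSON map `{"<index>": "<label>"}`.  The packaged deterministic
   backend labels by sentiment-cue lexicon and is exact on synthetic text;
   adapters for real LLMs satisfy the same contract but are never required
   by tests.  Raw outputs pass through a *total* parser: every string
   yields, per sentence, a label or exactly one NA subtype, by ordered
   rules (first match wins):

   * value is exactly one label → labeled;
   * two sentiment words, or a hyphen/slash-joined pair → `TWO_LABELS`;
   * one sentiment word plus extra text → `EXTRACT`;
   * refusal phrasing ("cannot", "will not") → `REFUSE`;
   * inability phrasing ("unable", "incomplete", "irrelevant") → `E_TEXT`;
   * anything else, including invalid JSON and missing indices → `ERROR`.

   The ordering is a package decision: the taxonomy names the categories
   but not a classifier, so the rules were chosen to reproduce the
   documented example strings.  `EXTRACT` values are recovered by a
   case-insensitive search for the three label strings (one distinct hit
   recovers; two reclassify as `TWO_LABELS`).  `TWO_LABELS`, `ERROR` and
   `REFUSE` sentences are rerun exactly once with a strict-JSON prompt
   (the strict wording is packaged configuration, not source-verbatim).
   Sentences still NA are retained — they count in the NSR denominator —
   while `E_TEXT` sentences are removed from the corpus.  Disposition
   counts are conserved and asserted on every call.

6. **Cohorts and covariates.** Patients whose primary ICD-10 code at the
   index note maps to the schizophrenia-spectrum CCSR category form the
   SCZ cohort; anxiety, bipolar, depressive, and trauma-related primaries
   with no SCZ code anywhere in their history form the controls; everyone
   else is excluded with exactly one reason code.  Trauma and substance
   history flags require a qualifying code strictly *before* the index
   date — same-day codes do not count (the source is silent; strict-before
   is the package's documented choice).  Race and ethnicity merge into six
   categories with Hispanic/Latino ethnicity dominating and small groups
   aggregated into Some Other Race; unrecognized values also land there
   (with a warning) rather than excluding the patient.  SES is the median
   household income of the patient's zip code; the packaged lookup is
   synthetic (labeled so in its filename) and spans $21,846–$250,000,
   which is validated at load time.  Ages outside 1–100 years (computed as
   floor whole years) are excluded as data-entry errors.

7. **Models.** Model 1 is
   `SCZ ~ age + sex*race_ethnicity*ses_z + trauma*substance + nsr +
   nsr:race_ethnicity + nsr:sex + nsr:ses_z` with treatment coding at
   White/Female references; Model 2 removes the four NSR terms (a strict
   subset, asserted by test).  Odds ratios are exact exponentials of
   coefficients; confidence bounds exponentiate `estimate ± 1.96·se`, and
   are always printed low–high.  Per-diagnosis univariate models regress
   each diagnosis indicator on the NSR alone.  Post-hoc group comparisons
   use Fisher's one-way ANOVA with partial omega-squared
   `(SSb − dfb·MSw)/(SSb + (N − dfb)·MSw)`.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| word-count bounds | 500 / 3000 | words | published note-length filter, inclusive |
| minimum sentences | 4 | sentences | published sentence filter |
| age bounds | 1 / 100 | years | published data-entry guard, inclusive |
| backend temperature / seed | 0.001 / 42 | — | published reproducibility settings |
| rerun attempts | 1 | — | a single described rerun pass |
| SES scaling | z-score | sd | scaling unstated; shared by generator and fitter |
| NSR scaling | raw | ratio on [0,1] | unit unstated; shared by generator and fitter |
| CI multiplier | 1.96 | — | 95% Wald intervals |

## The synthetic world

Generator defaults are the published cohort margins wherever those exist:
race/ethnicity and sex mixes pooled over the two published cohorts, age
mean ~37.5 (SD 16.7) truncated to 1–100, SES from a synthetic zip→income
table whose draw reproduces the published mean (~$83k) and SD (~$39k),
history-flag rates 43.6% (trauma) and 12.1% (substance), and per-patient
negative-sentence propensity Beta-distributed with the published group
moments (SCZ 0.28/0.14, control 0.22/0.13, pooled for single-cohort
scenarios).  Where the source is silent, values are fixed once as
realistic choices and documented here:

* **Sentence counts** follow a negative binomial with mean 28 and size 13
  (SD ≈ 9.3, matching the published per-patient sentence moments), floored
  at 8 and capped at 60; only group means are published, so the law itself
  is a package choice.
* **Non-negative sentences** split 75% neutral / 25% positive; the split
  is unpublished.
* **Irrelevant filler** is planted at 10% per note.
* **Control-category shares** in the univariate scenario (anxiety 22%,
  bipolar 11%, depression 22%, trauma 17% of the sample) are unpublished;
  the SCZ share (28%) is the published one.
* **Diagnosis indicators are independent draws** — one logistic model per
  outcome — rather than one mutually exclusive primary diagnosis.  This
  makes each univariate fit correctly specified, so recovery targets are
  well defined; it departs from the real cohort structure, where the
  categories partition patients.
* **Intercepts** left unset are centered so the mean linear predictor hits
  the logit of the target prevalence; recovery targets concern slopes, not
  intercepts.
* In the full-model scenario, effects the source reports are used as
  generating values (NSR OR 1.34; Male 1.14; Black×Male 1.08; Asian×Male
  1.20; Trauma×Substance 1.11); effects reported only as
  significant-with-direction (NSR×race, race×SES, three-way SES terms,
  the trauma and substance main effects) are given plausible magnitudes,
  and non-significant effects are zero.

Sentence templates embed unambiguous lexicon cues so the deterministic
backend reproduces gold labels exactly; with malformation rates at zero
the pipeline NSR equals the gold NSR *per note*, exactly.  A green
end-to-end test therefore establishes the plumbing — extraction, splitting,
filtering, parsing, counting — not any claim about LLM labeling quality on
real clinical language, which the template bank does not emulate (no
negation scope, no misspellings, no jargon, no document-level context).

## Numerical and testing choices

* Ties and degenerate inputs: empty notes yield empty section sets; a
  patient with zero retained sentences is an error (the note filters must
  have dropped them); constant NSR or single-level outcomes abort the
  fits; zero within-group variance aborts the ANOVA; a non-positive
  partial omega-squared is reported as computed with a `clamped` flag.
* The NSR is stored at full precision and only rounded for display, since
  it enters regressions.
* Logistic fits are plain `glm` maximum likelihood; fits are flagged on
  non-convergence or fitted probabilities within 1e-10 of 0/1
  (separation), never silently returned.  McFadden's pseudo-R² and the
  likelihood-ratio chi-square are reported because the source's "R²/F"
  for logistic models does not name a statistic family.
* Parameter-recovery tests run 50 seeded replicates scaled down to
  n = 6,000–12,000 (the full scenario sizes would dominate the suite's
  budget).  Coverage of a 95% CI observed 50 times has binomial noise of
  ±3 percentage points, so a hard per-coefficient 0.90 cut would fail
  roughly 9% of healthy runs; the 0.90 bound is asserted on the pooled
  150 trials, with a 3-sigma (0.85) guard per coefficient.
* Recovered odds ratios in the acceptance report are single fits at the
  prescribed sizes (50,000 / 100,000).  At those sizes the reference-level
  NSR main effect in the fully interacted model carries a standard error
  of ~0.17 on the OR scale, so point recovery is intrinsically noisy even
  though the generating value falls inside the fitted 95% CI with the
  nominal 95% frequency.

## Known limitations

* The relevance heuristic captures only the documented failure categories
  of the original trained classifier.
* The packaged CCSR map is a ~50-code subset spanning the referenced
  categories; a full CCSR export can be supplied through `load_ccsr(path)`.
* Age enters the models linearly; quartile-specific age odds reported for
  the source model imply a transformation it does not state, and that
  claim is not targeted.
* One note per patient; no longitudinal modeling beyond the pre-index
  history flags.
* The zip→income table is synthetic; real census joins are out of scope.
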
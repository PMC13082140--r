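## Sentiment lexicon and sentence template banks.
##
## The synthetic note generator and the deterministic labeling backend share
## this vocabulary: every negative/positive template carries at least one cue
## from its class and none from the other, so on synthetic text the lexicon
## backend reproduces the planted gold labels exactly.  Neutral sentences
## carry no cue and fall through to the default class.

#' Sentiment cue lexicon used by the deterministic backend
#'
#' @return named list with character vectors `negative` and `positive`
#'   (neutral is the cue-free default class).
#' @export
sentiment_lexicon <- function() {
  list(
    negative = c(
      "agitated", "hostile", "noncompliant", "uncooperative", "guarded",
      "irritable", "aggressive", "malodorous", "disheveled", "threatening",
      "poor insight", "poor judgment", "refuses", "suspicious", "evasive"
    ),
    positive = c(
      "cooperative", "pleasant", "engaged", "motivated", "insightful",
      "appreciative", "well-groomed", "friendly", "calm", "receptive"
    )
  )
}

## One-sentence templates.  Constraints that downstream stages rely on:
## single terminal period, no internal sentence punctuation, no digits in
## phone-number shape outside the filler bank, no relevance-filter trigger
## words (call/fax/schedule/appointment) outside the filler bank.
note_templates <- function() {
  list(
    negative = c(
      "Pt was agitated and yelling at staff in the waiting area.",
      "He remains noncompliant with prescribed medications.",
      "Pt refuses to participate in the interview.",
      "She appeared disheveled and malodorous on exam.",
      "Pt demonstrates poor insight into her condition.",
      "He was hostile toward nursing staff throughout the encounter.",
      "Pt is irritable and easily provoked.",
      "He made threatening remarks toward his roommate.",
      "Pt was uncooperative during the assessment.",
      "She is guarded and suspicious of the treatment team.",
      "Pt shows poor judgment regarding his own safety.",
      "She was evasive when asked about substance use."
    ),
    neutral = c(
      "Pt presented to the ED accompanied by family.",
      "He reports difficulty sleeping for the past week.",
      "Pt has a documented history of asthma.",
      "She is currently prescribed sertraline at bedtime.",
      "Pt denies suicidal ideation at this time.",
      "He lives with his mother in the area.",
      "Pt reports auditory hallucinations beginning last month.",
      "She was seen previously at an outside clinic.",
      "Vital signs were reviewed and within normal limits.",
      "He arrived via ambulance from his residence.",
      "Pt states that symptoms started after a recent move.",
      "Family history is notable for mood disorder."
    ),
    positive = c(
      "Pt was cooperative and pleasant during the interview.",
      "She is motivated to continue outpatient treatment.",
      "Pt appeared well-groomed and engaged.",
      "He was insightful about his recent stressors.",
      "Pt is appreciative of the care provided.",
      "She remained calm and friendly throughout the exam.",
      "He is receptive to medication adjustment.",
      "Pt engaged openly and was cooperative with the plan."
    ),
    filler = c(
      "Please call 212-555-0100 to schedule follow up.",
      "Contact the outpatient clinic at 917-555-0188 for appointments.",
      "Fax records to 646-555-0142 upon request.",
      "Appointment scheduling is available Monday through Friday.",
      "Please call the referral line to confirm the appointment.",
      "Front desk can be reached at 718-555-0133 for scheduling."
    ),
    padding = c(
      "Continue current medications and monitor mental status overnight.",
      "Discussed disposition options with the attending physician on duty.",
      "Reassess in the morning and document any interval change.",
      "Maintain standard observation precautions per unit protocol.",
      "Nursing to record intake and sleep through the night."
    )
  )
}

## Section header synonyms.  `target` sections are extracted; `boundary`
## headers only terminate the preceding section (mirrors how a clinical
## sectionizer knows many section titles but the analysis keeps four).
section_headers <- function() {
  list(
    target = list(
      CC         = c("CC", "Chief Complaint"),
      HPI        = c("HPI", "History of Present Illness"),
      MSE        = c("MSE", "Mental Status Exam", "Mental Status Examination"),
      COLLATERAL = c("Collateral", "Collateral Information")
    ),
    boundary = c(
      "Plan", "Medications", "Assessment", "ROS", "Review of Systems",
      "Past Medical History", "Allergies", "Labs", "Disposition",
      "Triage", "Vitals", "Social History", "Family History",
      "Physical Exam", "ED Course"
    )
  )
}
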
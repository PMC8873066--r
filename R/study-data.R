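# Bundled questionnaire data from the three-clinic FESS table-setup study
# (clinics insel, acqua, ukl; five scrub nurses interviewed per clinic).
# Per-participant answers were never published; with n = 5 per clinic each
# printed per-clinic percentage is an exact multiple of 20, so the yes-counts
# below (count = percent / 20) reconstruct the summary tables exactly.

#' Questionnaire of the FESS table-setup study
#'
#' The closed yes/no questions of the bundled case study: Q1.x/Q2.x probe the
#' existence, authorship, documentation and accessibility of a general and a
#' FESS-specific table-setup standard (each chained on the previous answer
#' being yes), Q3–Q5 probe literature awareness and support for a written
#' standard, and Q6.1–Q6.5 ask which factors influence the participant's own
#' initial setup. Question texts are paraphrases.
#'
#' @return A [question_specs()] data frame with 16 questions.
#' @seealso [fess_study_counts()]
#' @export
fess_study_questions <- function() {
  question_specs(data.frame(
    question_id = c("Q1.1", "Q1.2", "Q1.3", "Q1.4",
                    "Q2.1", "Q2.2", "Q2.3", "Q2.4",
                    "Q3", "Q4", "Q5",
                    "Q6.1", "Q6.2", "Q6.3", "Q6.4", "Q6.5"),
    text = c(
      "A general table-setup standard exists in the team",
      "Knows who made the general standard",
      "The general standard is written down",
      "Has access to the written general standard",
      "A FESS-specific table-setup standard exists in the team",
      "Knows who made the FESS standard",
      "The FESS standard is written down",
      "Has access to the written FESS standard",
      "Knows literature describing table setup for an operation",
      "Would support a written per-operation setup standard",
      "A written standard could help trainees and new entrants",
      "Influence: the individual surgeon",
      "Influence: chance / daily mood",
      "Influence: personal preference",
      "Influence: own training",
      "Influence: the in-house standard"),
    depends_on = c("", "Q1.1", "Q1.1;Q1.2", "Q1.1;Q1.2;Q1.3",
                   "", "Q2.1", "Q2.1;Q2.2", "Q2.1;Q2.2;Q2.3",
                   "", "", "",
                   "", "", "", "", ""),
    stringsAsFactors = FALSE
  ))
}

#' Questionnaire yes-counts of the FESS table-setup study
#'
#' Per-clinic yes-counts for the questions of [fess_study_questions()],
#' n = 5 participants per clinic, reconstructed from the study's per-clinic
#' agreement percentages (count = percent / 20).
#'
#' @return A [response_counts()] data frame (3 clinics x 16 questions).
#' @export
fess_study_counts <- function() {
  yes <- list(
    #          insel acqua ukl
    "Q1.1" = c(2, 3, 3),
    "Q1.2" = c(2, 1, 1),
    "Q1.3" = c(2, 1, 1),
    "Q1.4" = c(2, 0, 1),
    "Q2.1" = c(2, 1, 2),
    "Q2.2" = c(1, 1, 2),
    "Q2.3" = c(1, 0, 2),
    "Q2.4" = c(1, 0, 2),
    "Q3"   = c(2, 1, 4),
    "Q4"   = c(4, 2, 5),
    "Q5"   = c(4, 2, 5),
    "Q6.1" = c(1, 1, 3),
    "Q6.2" = c(0, 0, 0),
    "Q6.3" = c(4, 5, 5),
    "Q6.4" = c(3, 3, 4),
    "Q6.5" = c(3, 1, 1)
  )
  clinics <- c("insel", "acqua", "ukl")
  response_counts(data.frame(
    clinic_id = rep(clinics, times = length(yes)),
    question_id = rep(names(yes), each = length(clinics)),
    yes_count = unlist(yes, use.names = FALSE),
    n = 5,
    stringsAsFactors = FALSE
  ))
}
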
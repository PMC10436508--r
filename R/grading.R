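#' Severity grading configuration
#'
#' The clinical convention grades effusions by the maximal width at
#' end-diastole: small below 1 cm, moderate 1–2 cm, large above 2 cm.
#' The boundary convention here is SMALL = (presence_floor, 1), MODERATE =
#' \[1, 2\] (the "1–2 cm" bin read as inclusive, consistent with the
#' strict "<1" and ">2" neighbours), LARGE = (2, Inf). `presence_floor`
#' defaults to 0 — any positive width counts as effusion present — but can
#' be raised because segmentation specks can produce tiny nonzero widths.
#'
#' @param presence_floor Widths at or below this (cm) grade as NONE.
#' @param small_upper,moderate_upper Bin edges in cm.
#' @return List of class `grading_config`.
#' @export
grading_config <- function(presence_floor = 0, small_upper = 1, moderate_upper = 2) {
  if (!(presence_floor >= 0 && presence_floor < small_upper &&
        small_upper < moderate_upper)) {
    stop("need 0 <= presence_floor < small_upper < moderate_upper")
  }
  structure(list(presence_floor = presence_floor, small_upper = small_upper,
                 moderate_upper = moderate_upper),
            class = "grading_config")
}

#' Effusion severity grades
#' @export
EFFUSION_GRADES <- c("NONE", "SMALL", "MODERATE", "LARGE")

#' Grade an effusion width
#'
#' Monotone step function of the calibrated width: NONE at or below the
#' presence floor, then SMALL (< 1 cm), MODERATE (1–2 cm inclusive) and
#' LARGE (> 2 cm) by default. Vectorised.
#'
#' @param width_cm Non-negative width(s) in cm.
#' @param config A [grading_config()].
#' @return Ordered factor with levels NONE < SMALL < MODERATE < LARGE.
#' @examples
#' grade_effusion(c(0, 0.5, 1.0, 1.7, 2.5))
#' @export
grade_effusion <- function(width_cm, config = grading_config()) {
  if (anyNA(width_cm) || any(width_cm < 0)) {
    stop("width_cm must be non-negative")
  }
  g <- ifelse(width_cm <= config$presence_floor, "NONE",
       ifelse(width_cm < config$small_upper, "SMALL",
       ifelse(width_cm <= config$moderate_upper, "MODERATE", "LARGE")))
  factor(g, levels = EFFUSION_GRADES, ordered = TRUE)
}

#' Continuous detection score for ROC analysis
#'
#' The calibrated width itself is the detection score for both the
#' "effusion present" and the "moderate or worse" dichotomies: ROC/AUC only
#' use the score ordering, and the width orders cases exactly as any
#' monotone transform of it would.
#'
#' @param width_cm Non-negative width(s) in cm.
#' @return `width_cm`, unchanged.
#' @export
presence_score <- function(width_cm) {
  if (anyNA(width_cm) || any(width_cm < 0)) stop("width_cm must be non-negative")
  width_cm
}
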
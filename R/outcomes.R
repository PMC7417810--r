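#' IAPT outcome calculus
#'
#' Outcome definitions used in national IAPT reporting, computed from
#' baseline and end-of-treatment PHQ-9 (depression, 0-27) and GAD-7
#' (anxiety, 0-21) scores:
#'
#' * caseness: PHQ-9 >= 10 or GAD-7 >= 8;
#' * reliable improvement: a drop of >= 6 on PHQ-9 or >= 4 on GAD-7, the
#'   measurement-error thresholds, with (by default) no reliable increase
#'   on either scale;
#' * deterioration: a rise of >= 6 on PHQ-9 or >= 4 on GAD-7;
#' * recovery: caseness at baseline and below caseness on both scales at
#'   the end of treatment;
#' * reliable recovery: recovery plus reliable improvement;
#' * attrition: dropping out of or declining treatment after more than two
#'   sessions.
#'
#' All score arguments are vectorized and validated against instrument
#' ranges.
#'
#' @param phq,gad Baseline PHQ-9 / GAD-7 scores.
#' @param phq0,gad0,phq1,gad1 Baseline (`0`) and final (`1`) scores.
#' @param rule `"strict"` (default): reliable improvement additionally
#'   requires no reliable increase on either scale, so improvement and
#'   deterioration are mutually exclusive. `"either"`: the literal
#'   either-scale reading without that clause.
#' @name outcome_calculus
NULL

check_scores <- function(phq, gad) {
  if (any(is.na(phq) | is.na(gad)))
    stop("scores must not be missing")
  if (any(phq < 0 | phq > 27)) stop("PHQ-9 scores must lie in [0, 27]")
  if (any(gad < 0 | gad > 21)) stop("GAD-7 scores must lie in [0, 21]")
  invisible(TRUE)
}

# reliable-change thresholds (points) on each instrument
.RCI_PHQ <- 6L
.RCI_GAD <- 4L
# caseness cut-offs
.CASE_PHQ <- 10L
.CASE_GAD <- 8L

#' @rdname outcome_calculus
#' @return Logical vector(s).
#' @export
is_case <- function(phq, gad) {
  check_scores(phq, gad)
  phq >= .CASE_PHQ | gad >= .CASE_GAD
}

#' @rdname outcome_calculus
#' @export
deterioration <- function(phq0, gad0, phq1, gad1) {
  check_scores(phq0, gad0); check_scores(phq1, gad1)
  (phq1 - phq0) >= .RCI_PHQ | (gad1 - gad0) >= .RCI_GAD
}

#' @rdname outcome_calculus
#' @export
reliable_improvement <- function(phq0, gad0, phq1, gad1,
                                 rule = c("strict", "either")) {
  rule <- match.arg(rule)
  check_scores(phq0, gad0); check_scores(phq1, gad1)
  imp <- (phq0 - phq1) >= .RCI_PHQ | (gad0 - gad1) >= .RCI_GAD
  if (rule == "strict")
    imp <- imp & !deterioration(phq0, gad0, phq1, gad1)
  imp
}

#' @rdname outcome_calculus
#' @export
recovery <- function(phq0, gad0, phq1, gad1) {
  check_scores(phq0, gad0); check_scores(phq1, gad1)
  is_case(phq0, gad0) & phq1 < .CASE_PHQ & gad1 < .CASE_GAD
}

#' @rdname outcome_calculus
#' @export
reliable_recovery <- function(phq0, gad0, phq1, gad1,
                              rule = c("strict", "either")) {
  recovery(phq0, gad0, phq1, gad1) &
    reliable_improvement(phq0, gad0, phq1, gad1, rule = rule)
}

#' @rdname outcome_calculus
#' @param n_sessions Number of treatment sessions attended.
#' @param end_status One of `"completed"`, `"dropped_out"`, `"declined"`,
#'   `"other"`.
#' @export
attrition <- function(n_sessions, end_status) {
  if (any(n_sessions < 0)) stop("n_sessions must be non-negative")
  ok <- end_status %in% c("completed", "dropped_out", "declined", "other")
  if (!all(ok)) stop("unknown end_status: ",
                     paste(unique(end_status[!ok]), collapse = ", "))
  end_status %in% c("dropped_out", "declined") & n_sessions > 2
}

#' Compute all outcome flags for a cohort
#'
#' One row per case: baseline caseness, recovery, reliable improvement,
#' reliable recovery, deterioration, attrition.
#'
#' @param cohort Data frame with columns `phq`, `gad` (baseline),
#'   `final_phq`, `final_gad`, `n_sessions`, `end_status`.
#' @inheritParams outcome_calculus
#' @return Data frame of logical columns `caseness_baseline`, `recovered`,
#'   `reliably_improved`, `reliably_recovered`, `deteriorated`, `attrition`.
#' @export
outcome_flags <- function(cohort, rule = c("strict", "either")) {
  rule <- match.arg(rule)
  data.frame(
    caseness_baseline = is_case(cohort$phq, cohort$gad),
    recovered = recovery(cohort$phq, cohort$gad,
                         cohort$final_phq, cohort$final_gad),
    reliably_improved = reliable_improvement(
      cohort$phq, cohort$gad, cohort$final_phq, cohort$final_gad, rule),
    reliably_recovered = reliable_recovery(
      cohort$phq, cohort$gad, cohort$final_phq, cohort$final_gad, rule),
    deteriorated = deterioration(cohort$phq, cohort$gad,
                                 cohort$final_phq, cohort$final_gad),
    attrition = attrition(cohort$n_sessions, cohort$end_status))
}

#' Apply the cohort inclusion criteria
#'
#' Keeps cases that (i) have at most two of the nine indicators missing,
#' (ii) attended at least two sessions and have a final score (so an
#' outcome can be computed), and (iii) meet baseline caseness. Exclusion
#' reasons are tallied with fixed precedence missingness > sessions >
#' caseness, so each excluded case counts once.
#'
#' @param cohort Data frame with the indicator columns plus `final_phq`,
#'   `final_gad`, `n_sessions`.
#' @param schema An [indicator_schema].
#' @return List with `included` (data frame, input order preserved),
#'   `tally` (named counts: `missingness`, `sessions`, `caseness`), and
#'   `excluded_reason` (per-input-row factor, `NA` for kept rows).
#' @export
apply_inclusion <- function(cohort, schema = default_schema()) {
  nm <- c(cont_names(schema), bin_names(schema))
  miss <- rowSums(is.na(as.matrix(cohort[nm])))
  has_follow <- !is.na(cohort$final_phq) & !is.na(cohort$final_gad) &
    cohort$n_sessions >= 2
  case_ok <- ifelse(is.na(cohort$phq) | is.na(cohort$gad), FALSE,
                    cohort$phq >= .CASE_PHQ | cohort$gad >= .CASE_GAD)
  reason <- rep(NA_character_, nrow(cohort))
  reason[!case_ok] <- "caseness"
  reason[!has_follow] <- "sessions"
  reason[miss > 2] <- "missingness"
  keep <- is.na(reason)
  tally <- c(missingness = sum(reason == "missingness", na.rm = TRUE),
             sessions = sum(reason == "sessions", na.rm = TRUE),
             caseness = sum(reason == "caseness", na.rm = TRUE))
  list(included = cohort[keep, , drop = FALSE], tally = tally,
       excluded_reason = reason)
}
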
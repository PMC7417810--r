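#' Classify the intensity of a care episode
#'
#' `LI` or `HI` when every session of the episode was delivered at that
#' intensity, `mixed` when the patient was stepped up or down.
#'
#' @param intensities Character vector of per-session intensities
#'   (`"LI"`/`"HI"`), in session order.
#' @return `"LI"`, `"HI"` or `"mixed"`.
#' @export
classify_intensity <- function(intensities) {
  if (!length(intensities)) stop("episode has no sessions")
  if (!all(intensities %in% c("LI", "HI")))
    stop("intensities must be 'LI' or 'HI'")
  u <- unique(intensities)
  if (length(u) == 1L) u else "mixed"
}

#' Main treatment modality of an episode
#'
#' The episode's main modality is the modality of the last session, provided
#' the episode was delivered at a single intensity and that modality covers
#' strictly more than half of all sessions; otherwise `NA`.
#'
#' @param modalities Character vector of per-session modality codes (e.g.
#'   `"GSH"`, `"cCBT"`, `"CBT"`, `"Counselling"`, `"IPT"`), in session order.
#' @param intensities Matching per-session intensities.
#' @return Modality code or `NA_character_`.
#' @export
main_modality <- function(modalities, intensities) {
  if (length(modalities) != length(intensities) || !length(modalities))
    stop("modalities and intensities must be non-empty and equal length")
  if (classify_intensity(intensities) == "mixed") return(NA_character_)
  last <- modalities[length(modalities)]
  if (sum(modalities == last) > length(modalities) / 2) last else NA_character_
}

#' Propensity scores from profile-membership probabilities
#'
#' Logistic regression of treatment assignment on the posterior membership
#' probabilities (the last profile's probability dropped, as the eight sum
#' to one) plus an intercept; returns the fitted treatment probabilities.
#'
#' @param posteriors n x C matrix of posterior membership probabilities.
#' @param treated Logical vector, `TRUE` for the treated arm.
#' @return Numeric vector of propensity scores in (0, 1).
#' @export
estimate_propensity <- function(posteriors, treated) {
  posteriors <- as.matrix(posteriors)
  if (nrow(posteriors) != length(treated)) stop("inputs must be aligned")
  if (!any(treated) || all(treated))
    stop("need at least one treated and one control case")
  Xp <- posteriors[, -ncol(posteriors), drop = FALSE]
  colnames(Xp) <- paste0("p", seq_len(ncol(Xp)))
  df <- data.frame(treated = as.numeric(treated), Xp)
  fit <- withCallingHandlers(
    stats::glm(treated ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        stop("perfect separation: propensity model is not identified",
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  ps <- as.numeric(stats::fitted(fit))
  if (any(ps > 1 - 1e-7) || any(ps < 1e-7))
    stop("perfect separation: propensity model is not identified")
  ps
}

#' Greedy caliper matching on the propensity score
#'
#' 1:1 nearest-neighbour matching: treated cases are processed in
#' descending propensity order and each is paired with the control whose
#' score is nearest (ties to the lower control index) provided the absolute
#' difference is within the caliper (boundary inclusive). With replacement
#' (the default) a control may serve several treated cases; without, each
#' control is used at most once. Treated cases with no admissible control
#' are reported unmatched.
#'
#' @param scores Propensity score per case.
#' @param treated Logical treatment indicator per case.
#' @param caliper Maximum admissible score distance (default 0.001, on the
#'   probability scale).
#' @param with_replacement Reuse controls (default `TRUE`).
#' @return A `matched_cohort`: list with `pairs` (data frame `treated`,
#'   `control`, `distance`), `unmatched_treated` (indices), `scores`,
#'   `caliper`, `loss_fraction` (treated cases lost to matching).
#' @export
match_propensity <- function(scores, treated, caliper = 0.001,
                             with_replacement = TRUE) {
  if (caliper <= 0) stop("caliper must be positive")
  if (length(scores) != length(treated)) stop("inputs must be aligned")
  t_idx <- which(treated)
  c_idx <- which(!treated)
  ord <- t_idx[order(scores[t_idx], decreasing = TRUE)]
  avail <- rep(TRUE, length(c_idx))
  pairs <- list(); unmatched <- integer(0)
  for (ti in ord) {
    pool <- which(avail)
    if (!length(pool)) { unmatched <- c(unmatched, ti); next }
    d <- abs(scores[c_idx[pool]] - scores[ti])
    best <- pool[which.min(d)]          # which.min takes the first = lowest index
    if (min(d) <= caliper + 1e-12) {    # boundary inclusive, float-safe
      pairs[[length(pairs) + 1L]] <- data.frame(
        treated = ti, control = c_idx[best], distance = min(d))
      if (!with_replacement) avail[best] <- FALSE
    } else unmatched <- c(unmatched, ti)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(treated = integer(0), control = integer(0),
               distance = numeric(0))
  stopifnot(all(pairs$distance <= caliper + 1e-12))  # caliper contract
  structure(list(pairs = pairs, unmatched_treated = sort(unmatched),
                 scores = scores, caliper = caliper,
                 loss_fraction = length(unmatched) / max(1L, length(t_idx))),
            class = "matched_cohort")
}

#' Outcome odds ratio over a matched cohort
#'
#' Builds the 2x2 outcome-by-arm table over the matched sample (each
#' control counted once per use) and estimates the odds ratio with the same
#' Woolf-interval estimator as [profile_outcome_or()].
#'
#' @param matched A `matched_cohort` from [match_propensity()].
#' @param flags Outcome-flag data frame indexed like the original cohort.
#' @param outcome Flag column name.
#' @return One-row odds-ratio data frame (treated arm vs control arm).
#' @export
compare_matched_outcomes <- function(matched, flags, outcome) {
  if (!nrow(matched$pairs)) stop("matched cohort has no pairs")
  yt <- flags[[outcome]][matched$pairs$treated]
  yc <- flags[[outcome]][matched$pairs$control]
  or_from_table(sum(yt), sum(!yt), sum(yc), sum(!yc),
                label = paste0(outcome, ": treated vs matched control"))
}
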
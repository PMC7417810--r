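#' Outcome rates by secondary profile within one primary profile
#'
#' Cases whose primary profile equals `primary` are grouped by their
#' secondary (second-highest-probability) profile. Strata with fewer than
#' `min_n` cases are excluded from the rate rows but tallied so that
#' included plus excluded counts reproduce the all-cases total.
#'
#' @param allocations A `profile_allocation`.
#' @param flags Outcome-flag data frame aligned to the allocations.
#' @param primary Primary profile label or index.
#' @param outcomes Character vector of flag columns to report.
#' @param min_n Minimum stratum size to report (default 10).
#' @return List with `rows` (secondary profile, n, one proportion column per
#'   outcome), `excluded` (secondary profile, n), and `total` (the all-cases
#'   summary row). `sum(rows$n) + sum(excluded$n) == total$n` always.
#' @export
secondary_table <- function(allocations, flags, primary,
                            outcomes = c("reliably_recovered", "deteriorated"),
                            min_n = 10L) {
  labs <- allocations$labels
  jp <- if (is.character(primary)) match(primary, labs) else primary
  if (is.na(jp)) stop("unknown primary profile")
  idx <- which(allocations$primary == jp)
  if (!length(idx)) stop("primary profile has no cases")
  sec <- allocations$secondary[idx]
  mk_row <- function(sel, label) {
    row <- list(secondary = label, n = length(sel))
    for (f in outcomes) row[[f]] <- mean(flags[[f]][sel])
    as.data.frame(row)
  }
  rows <- list(); excl <- list()
  for (j in sort(unique(sec))) {
    sel <- idx[sec == j]
    if (length(sel) >= min_n) {
      rows[[length(rows) + 1L]] <- mk_row(sel, labs[j])
    } else {
      excl[[length(excl) + 1L]] <- data.frame(secondary = labs[j],
                                              n = length(sel))
    }
  }
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(secondary = character(0), n = integer(0))
  excl <- if (length(excl)) do.call(rbind, excl) else
    data.frame(secondary = character(0), n = integer(0))
  total <- mk_row(idx, paste0("All ", labs[jp], " cases"))
  stopifnot(sum(rows$n) + sum(excl$n) == total$n)
  list(rows = rows, excluded = excl, total = total)
}

#' Outcome split by whether the secondary profile is a flagged profile
#'
#' For every primary profile other than `flag_profile`, reports the size and
#' outcome proportion of the cases whose secondary profile is
#' `flag_profile` against all remaining cases of that primary profile
#' (pooling every other secondary).
#'
#' @inheritParams secondary_table
#' @param flag_profile Profile label or index to split on.
#' @param outcome Single flag column name.
#' @return Data frame: `profile`, `n_not_flag`, `rate_not_flag`, `n_flag`,
#'   `rate_flag`.
#' @export
secondary_flag_split <- function(allocations, flags, flag_profile,
                                 outcome = "deteriorated") {
  labs <- allocations$labels
  jf <- if (is.character(flag_profile)) match(flag_profile, labs) else
    flag_profile
  if (is.na(jf)) stop("unknown flag profile")
  rows <- list()
  for (j in setdiff(seq_along(labs), jf)) {
    idx <- which(allocations$primary == j)
    is_flag <- allocations$secondary[idx] == jf
    nf <- sum(is_flag); nn <- sum(!is_flag)
    rows[[length(rows) + 1L]] <- data.frame(
      profile = labs[j],
      n_not_flag = nn,
      rate_not_flag = if (nn > 0) mean(flags[[outcome]][idx[!is_flag]])
                      else NA_real_,
      n_flag = nf,
      rate_flag = if (nf > 0) mean(flags[[outcome]][idx[is_flag]])
                  else NA_real_)
  }
  do.call(rbind, rows)
}
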
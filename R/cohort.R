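#' Profile prevalence by year
#'
#' Per-year proportion of cases allocated to each primary profile; rows sum
#' to one within each year (zero rows with `n = 0` for empty strata).
#'
#' @param allocations A `profile_allocation` from [allocate()].
#' @param years Vector of year labels, one per case.
#' @return Data frame: `year`, `n`, one proportion column per profile label.
#' @export
prevalence_by_year <- function(allocations, years) {
  if (length(years) != length(allocations$primary))
    stop("years and allocations must have equal length")
  labs <- allocations$labels
  yl <- sort(unique(years))
  out <- lapply(yl, function(y) {
    idx <- years == y
    n <- sum(idx)
    p <- if (n == 0) rep(0, length(labs)) else
      tabulate(allocations$primary[idx], nbins = length(labs)) / n
    c(list(year = y, n = n), stats::setNames(as.list(p), labs))
  })
  do.call(rbind, lapply(out, as.data.frame))
}

#' Outcome rates stratified by primary profile
#'
#' @param allocations A `profile_allocation`.
#' @param flags Outcome-flag data frame from [outcome_flags()], aligned to
#'   the allocations.
#' @return Data frame: `profile`, `n`, then for each flag column its count
#'   and proportion.
#' @export
outcome_rates_by_profile <- function(allocations, flags) {
  if (nrow(flags) != length(allocations$primary))
    stop("flags and allocations must be aligned")
  labs <- allocations$labels
  rows <- lapply(seq_along(labs), function(j) {
    idx <- allocations$primary == j
    n <- sum(idx)
    row <- list(profile = labs[j], n = n)
    for (f in names(flags)) {
      cnt <- sum(flags[[f]][idx])
      row[[paste0(f, "_n")]] <- cnt
      row[[paste0(f, "_prop")]] <- if (n > 0) cnt / n else 0
    }
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

# Woolf CI odds ratio from a 2x2 table; Haldane-Anscombe +0.5 on zero cells.
# a,b = outcome yes/no in group 1; c,d = outcome yes/no in group 2.
or_from_table <- function(a, b, c, d, label = "") {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5
                                 c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- log(or) / se
  data.frame(comparison = label, or = or,
             ci_low = exp(log(or) - 1.96 * se),
             ci_high = exp(log(or) + 1.96 * se),
             p = 2 * stats::pnorm(-abs(z)),
             a = a, b = b, c = c, d = d)
}

#' Between-profile odds ratio for an outcome
#'
#' Cross-product odds ratio from the 2x2 outcome-by-profile table with a
#' Woolf (log-scale Wald) 95 percent confidence interval — identical to the
#' exponentiated coefficient of a two-level logistic regression. Zero cells
#' receive the Haldane-Anscombe +0.5 correction.
#'
#' @param flags Outcome-flag data frame.
#' @param allocations A `profile_allocation`.
#' @param outcome Name of the flag column to compare.
#' @param profile_a,profile_b Profile labels or indices; the odds ratio is
#'   odds(`profile_a`) / odds(`profile_b`).
#' @return One-row data frame: `comparison`, `or`, `ci_low`, `ci_high`,
#'   `p`, cell counts `a`, `b`, `c`, `d`.
#' @export
profile_outcome_or <- function(flags, allocations, outcome,
                               profile_a, profile_b) {
  labs <- allocations$labels
  ja <- if (is.character(profile_a)) match(profile_a, labs) else profile_a
  jb <- if (is.character(profile_b)) match(profile_b, labs) else profile_b
  if (is.na(ja) || is.na(jb)) stop("unknown profile label")
  y <- flags[[outcome]]
  ia <- allocations$primary == ja; ib <- allocations$primary == jb
  if (!any(ia) || !any(ib)) stop("a compared profile has zero members")
  or_from_table(sum(y[ia]), sum(!y[ia]), sum(y[ib]), sum(!y[ib]),
                label = paste0(outcome, ": ", labs[ja], " vs ", labs[jb]))
}

#' Per-year, per-profile outcome rates with small-cell suppression
#'
#' @inheritParams outcome_rates_by_profile
#' @param years Year label per case.
#' @param outcome Flag column name.
#' @param min_cell Strata with `n < min_cell` (default 10) are flagged as
#'   suppressed and their rate set to `NA`.
#' @return Data frame: `year`, `profile`, `n`, `rate`, `suppressed`.
#' @export
yearly_stability <- function(allocations, flags, years, outcome,
                             min_cell = 10L) {
  labs <- allocations$labels
  yl <- sort(unique(years))
  rows <- list()
  for (y in yl) for (j in seq_along(labs)) {
    idx <- years == y & allocations$primary == j
    n <- sum(idx)
    supp <- n < min_cell
    rows[[length(rows) + 1L]] <- data.frame(
      year = y, profile = labs[j], n = n,
      rate = if (supp) NA_real_ else mean(flags[[outcome]][idx]),
      suppressed = supp)
  }
  do.call(rbind, rows)
}
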
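#' Read and write cohort tables
#'
#' Cohort CSV: comma-separated, UTF-8, header row, dot decimal, one row per
#' patient with the indicator columns plus any of `id`, `year`,
#' `true_profile`, `intensity`, `main_modality`, `n_sessions`, `final_phq`,
#' `final_gad`, `end_status`. Empty cells map to `NA` (unobserved).
#'
#' @param path CSV file path.
#' @param records Cohort data frame.
#' @param schema An [indicator_schema] used to validate required columns.
#' @return `read_cohort`: the cohort data frame. `write_cohort`: `path`,
#'   invisibly. A write-then-read round trip is field-identical.
#' @export
read_cohort <- function(path, schema = default_schema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  missing_cols <- setdiff(schema$names, names(df))
  if (length(missing_cols))
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (nm in c(schema$names, "final_phq", "final_gad", "n_sessions")) {
    if (!nm %in% names(df)) next
    v <- df[[nm]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(conv))
      if (length(bad))
        stop("non-numeric value in column '", nm, "' at row ",
             bad[1], ": '", v[bad[1]], "'")
      df[[nm]] <- conv
    }
  }
  df
}

#' @rdname read_cohort
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write per-session episode tables
#'
#' Episode CSV: one row per session with columns `id`, `session`,
#' `modality`, `intensity`.
#'
#' @param path CSV file path.
#' @param episodes Episode data frame.
#' @return The episode data frame / `path` invisibly.
#' @export
read_episodes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "session", "modality", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("episode file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}

#' @rdname read_episodes
#' @export
write_episodes <- function(episodes, path) {
  utils::write.csv(episodes, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' Configuration files are JSON (a YAML subset): any of the
#' [default_preset()] fields may be overridden; unspecified fields keep
#' their preset values.
#'
#' @param path JSON config path, or `NULL` for the default preset.
#' @return A `generator_config`.
#' @export
read_config <- function(path = NULL) {
  config <- default_preset()
  if (is.null(path)) return(config)
  ov <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in intersect(names(ov), c("n", "seed", "missing_rate",
                                    "year_labels", "year_weights")))
    config[[nm]] <- ov[[nm]]
  for (blk in intersect(names(ov), c("treatment", "sessions", "outcomes")))
    for (nm in names(ov[[blk]]))
      config[[blk]][[nm]] <- ov[[blk]][[nm]]
  if (!is.null(ov$model_file))
    config$model <- read_profile_model(ov$model_file)
  config
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a pipeline stage
#'
#' Reproducible driver tying the modules together. Subcommands:
#' `simulate` (synthetic cohort + episode CSVs), `fit` (EM fit, model
#' JSON), `allocate` (posterior allocation CSV), `outcomes` (inclusion +
#' outcome flags CSV), `stratify` (prevalence-by-year, outcome-by-profile
#' and yearly-stability CSVs), `match-compare` (propensity-matched LI-vs-HI
#' and CBT-vs-Counselling odds ratios), `secondary` (secondary-profile
#' tables), `summary-test` (between-sample tests from summary statistics).
#' Every output directory receives a `manifest.json` recording the
#' subcommand, seed, stage counts and output files; identical config and
#' seed give identical outputs.
#'
#' @param subcommand One of the stage names above.
#' @param config_path Optional JSON config overriding [default_preset()].
#' @param out_dir Output directory (created if needed).
#' @param seed Root seed; every randomized stage derives its stream from it.
#' @param n Cohort size for `simulate` (default from config).
#' @param cohort_path,episodes_path Input CSVs for analysis stages
#'   (default: the files `simulate` writes into `out_dir`).
#' @param C Number of profiles for `fit` (default 8).
#' @param min_cell Suppression threshold for `stratify` (default 10).
#' @param caliper Matching caliper for `match-compare` (default 0.001).
#' @param improvement_rule `"strict"` or `"either"` (see
#'   [outcome_calculus]).
#' @param n_starts EM restarts for `fit`.
#' @return The manifest list, invisibly; artifacts are written to
#'   `out_dir`.
#' @export
run_pipeline <- function(subcommand, config_path = NULL, out_dir = ".",
                         seed = NULL, n = NULL,
                         cohort_path = file.path(out_dir, "cohort.csv"),
                         episodes_path = file.path(out_dir, "episodes.csv"),
                         C = 8L, min_cell = 10L, caliper = 0.001,
                         improvement_rule = "strict", n_starts = 5L) {
  known <- c("simulate", "fit", "allocate", "outcomes", "stratify",
             "match-compare", "secondary", "summary-test")
  if (!subcommand %in% known)
    stop("unknown subcommand '", subcommand, "'; use one of: ",
         paste(known, collapse = ", "))
  config <- read_config(config_path)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(n)) config$n <- as.integer(n)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(command = subcommand, seed = config$seed,
                   config = if (is.null(config_path)) "default" else
                     config_path,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   counts = list(), outputs = character(0))
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    manifest$outputs <<- c(manifest$outputs, name)
    p
  }

  if (subcommand == "simulate") {
    sim <- generate_cohort(config, config$n, config$seed)
    write_cohort(sim$cohort, file.path(out_dir, "cohort.csv"))
    write_episodes(sim$episodes, file.path(out_dir, "episodes.csv"))
    manifest$outputs <- c("cohort.csv", "episodes.csv")
    manifest$counts <- list(n = nrow(sim$cohort),
                            n_sessions = nrow(sim$episodes))
  } else if (subcommand == "summary-test") {
    tab <- reproduce_sample_tests()
    emit(tab, "summary_tests.csv")
    manifest$counts <- list(rows = nrow(tab))
  } else {
    cohort <- read_cohort(cohort_path)
    manifest$counts$input <- nrow(cohort)
    if (subcommand == "fit") {
      fit <- fit_em(cohort, C, seed = config$seed, n_starts = n_starts)
      write_profile_model(fit, file.path(out_dir, "model.json"))
      manifest$outputs <- "model.json"
      manifest$counts$loglik <- attr(fit, "logLik")
    } else {
      model <- config$model
      # the missingness rule precedes every allocation
      n_miss <- rowSums(is.na(as.matrix(cohort[model$schema$names])))
      cohort <- cohort[n_miss <= 2L, , drop = FALSE]
      manifest$counts$missingness_excluded <- sum(n_miss > 2L)
      al <- allocate(cohort, model)
      if (subcommand == "allocate") {
        out <- data.frame(id = cohort$id,
                          primary = model$labels[al$primary],
                          secondary = model$labels[al$secondary],
                          max_prob = al$max_prob)
        probs <- as.data.frame(al$probs)
        names(probs) <- paste0("prob_", model$labels)
        emit(cbind(out, probs), "allocation.csv")
      } else {
        inc <- apply_inclusion(cohort)
        manifest$counts$excluded <- as.list(inc$tally)
        manifest$counts$included <- nrow(inc$included)
        keep <- is.na(inc$excluded_reason)
        flags <- outcome_flags(inc$included, rule = improvement_rule)
        al_inc <- allocate(inc$included[model$schema$names], model)
        if (subcommand == "outcomes") {
          emit(cbind(id = inc$included$id, flags), "outcome_flags.csv")
        } else if (subcommand == "stratify") {
          emit(prevalence_by_year(al, cohort$year), "prevalence_by_year.csv")
          emit(outcome_rates_by_profile(al_inc, flags),
               "outcome_rates_by_profile.csv")
          emit(yearly_stability(al_inc, flags, inc$included$year,
                                "reliably_recovered", min_cell = min_cell),
               "yearly_stability.csv")
        } else if (subcommand == "secondary") {
          st <- secondary_table(al_inc, flags, "LP6")
          emit(st$rows, "secondary_table.csv")
          emit(st$excluded, "secondary_table_excluded.csv")
          emit(secondary_flag_split(al_inc, flags, "LP6"),
               "secondary_flag_split.csv")
        } else if (subcommand == "match-compare") {
          res <- matched_comparisons(inc$included, al_inc, flags,
                                     caliper = caliper)
          emit(res$or_table, "matched_or.csv")
          emit(res$pairs, "matched_pairs.csv")
          manifest$counts$matched_pairs <- nrow(res$pairs)
        }
      }
    }
  }
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Propensity-matched treatment comparisons for a cohort
#'
#' Runs the two published within-cohort contrasts on an included cohort:
#' low- vs high-intensity treatment (stepped/mixed episodes excluded) and
#' CBT vs Counselling among pure-HI episodes with a defined main modality.
#' In each contrast the smaller arm is matched into the larger with 1:1
#' greedy caliper matching on the propensity score estimated from the
#' posterior membership probabilities.
#'
#' @param cohort Included cohort data frame (with `intensity`,
#'   `main_modality` columns).
#' @param allocations `profile_allocation` aligned to `cohort`.
#' @param flags Outcome flags aligned to `cohort`.
#' @param outcome Flag column to compare (default reliable recovery).
#' @param caliper Matching caliper (default 0.001).
#' @return List with `or_table` (one row per contrast: odds ratio of the
#'   HI / CBT arm vs its comparator, matched loss fraction) and `pairs`
#'   (matched index pairs per contrast).
#' @export
matched_comparisons <- function(cohort, allocations, flags,
                                outcome = "reliably_recovered",
                                caliper = 0.001) {
  run_one <- function(sel, arm, label) {
    idx <- which(sel)
    treated <- arm[sel]
    # smaller arm is matched into the larger
    if (sum(treated) > sum(!treated)) treated <- !treated
    ps <- estimate_propensity(allocations$probs[idx, , drop = FALSE],
                              treated)
    mc <- match_propensity(ps, treated, caliper = caliper)
    fl <- flags[idx, , drop = FALSE]
    or <- compare_matched_outcomes(mc, fl, outcome)
    # report the OR with the named first arm in the numerator
    flipped <- !identical(treated, arm[sel])
    if (flipped) {
      or <- or_from_table(or$c, or$d, or$a, or$b, label = label)
    } else or$comparison <- label
    or$loss_fraction <- mc$loss_fraction
    pairs <- data.frame(contrast = label,
                        treated = idx[mc$pairs$treated],
                        control = idx[mc$pairs$control],
                        distance = mc$pairs$distance)
    list(or = or, pairs = pairs)
  }
  li_hi <- run_one(cohort$intensity %in% c("LI", "HI"),
                   cohort$intensity == "HI",
                   paste0(outcome, ": HI vs LI"))
  cc_sel <- cohort$intensity == "HI" &
    !is.na(cohort$main_modality) &
    cohort$main_modality %in% c("CBT", "Counselling")
  cbt <- run_one(cc_sel, cohort$main_modality == "CBT" & cc_sel,
                 paste0(outcome, ": CBT vs Counselling"))
  list(or_table = rbind(li_hi$or, cbt$or),
       pairs = rbind(li_hi$pairs, cbt$pairs))
}
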
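#' Indicator schema for the profiling algorithm
#'
#' The default schema holds the nine routinely collected indicators the
#' profiling algorithm operates on: four continuous (depression severity
#' PHQ-9, anxiety severity GAD-7, functional impairment WSAS, age at
#' referral) and five dichotomous (phobia caseness, female gender,
#' psychotropic medication prescribed, welfare benefit receipt, non-white
#' ethnic group).
#'
#' @param names Character vector of indicator identifiers (unique).
#' @param kinds Character vector, one of `"continuous"` or `"binary"` per
#'   indicator.
#' @param ranges Named list mapping each continuous indicator to a closed
#'   interval `c(lo, hi)` on its raw instrument scale.
#' @return An object of class `indicator_schema`.
#' @examples
#' s <- default_schema()
#' s$names
#' @export
indicator_schema <- function(names, kinds, ranges) {
  stopifnot(is.character(names), length(names) == length(kinds))
  if (anyDuplicated(names)) stop("indicator names must be unique")
  if (!all(kinds %in% c("continuous", "binary")))
    stop("kinds must be 'continuous' or 'binary'")
  cont <- names[kinds == "continuous"]
  if (!setequal(names(ranges), cont))
    stop("ranges must be supplied for exactly the continuous indicators")
  for (nm in cont) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] >= r[2]) stop("range for ", nm, " must be c(lo, hi)")
  }
  structure(list(names = names, kinds = kinds, ranges = ranges[cont]),
            class = "indicator_schema")
}

#' @rdname indicator_schema
#' @export
default_schema <- function() {
  indicator_schema(
    names = c("phq", "gad", "wsas", "age",
              "phobia", "female", "medication", "welfare", "nonwhite"),
    kinds = c(rep("continuous", 4), rep("binary", 5)),
    ranges = list(phq = c(0, 27), gad = c(0, 21), wsas = c(0, 40),
                  age = c(16, 95))
  )
}

cont_names <- function(schema) schema$names[schema$kinds == "continuous"]
bin_names  <- function(schema) schema$names[schema$kinds == "binary"]

# numeric floors used throughout estimation
.VAR_FLOOR <- 1e-4     # floor on sigma^2
.RATE_CLIP <- 1e-6     # Bernoulli rates kept in [clip, 1 - clip]

#' Construct a latent profile model
#'
#' A finite mixture over `C` latent profiles with locally independent
#' indicators: Gaussian densities for the continuous items (on their raw
#' instrument scales) and Bernoulli masses for the binary items.
#'
#' @param weights Length-`C` mixing proportions; must be strictly positive
#'   and sum to one.
#' @param cont_means,cont_sds `C x n_cont` matrices of per-profile means and
#'   standard deviations for the continuous indicators (columns in schema
#'   order).
#' @param bin_rates `C x n_bin` matrix of per-profile Bernoulli rates for the
#'   binary indicators.
#' @param schema An [indicator_schema]; defaults to [default_schema()].
#' @param labels Optional length-`C` profile names; defaults to
#'   `LP1 ... LPC`.
#' @return An object of class `profile_model`.
#' @export
profile_model <- function(weights, cont_means, cont_sds, bin_rates,
                          schema = default_schema(), labels = NULL) {
  C <- length(weights)
  cont_means <- as.matrix(cont_means); cont_sds <- as.matrix(cont_sds)
  bin_rates <- as.matrix(bin_rates)
  if (is.null(labels)) labels <- paste0("LP", seq_len(C))
  m <- structure(
    list(C = C, weights = as.numeric(weights),
         cont_means = cont_means, cont_sds = cont_sds,
         bin_rates = bin_rates, schema = schema,
         labels = as.character(labels)),
    class = "profile_model")
  validate_profile_model(m)
  m
}

#' @rdname profile_model
#' @param model Object to validate.
#' @export
validate_profile_model <- function(model) {
  stopifnot(inherits(model, "profile_model"))
  C <- model$C
  nc <- length(cont_names(model$schema)); nb <- length(bin_names(model$schema))
  if (C < 1L) stop("C must be a positive integer")
  if (abs(sum(model$weights) - 1) > 1e-9)
    stop("mixing weights must sum to 1 (got ", sum(model$weights), ")")
  if (any(model$weights <= 0) || any(model$weights >= 1 + 1e-12))
    stop("mixing weights must lie in (0, 1)")
  if (!all(dim(model$cont_means) == c(C, nc)) ||
      !all(dim(model$cont_sds) == c(C, nc)) ||
      !all(dim(model$bin_rates) == c(C, nb)))
    stop("parameter matrix dimensions do not match C and the schema")
  if (any(model$cont_sds^2 < .VAR_FLOOR - 1e-12))
    stop("all sigma^2 must be >= the variance floor ", .VAR_FLOOR)
  if (any(model$bin_rates < .RATE_CLIP - 1e-12) ||
      any(model$bin_rates > 1 - .RATE_CLIP + 1e-12))
    stop("binary rates must lie in [", .RATE_CLIP, ", ", 1 - .RATE_CLIP, "]")
  if (length(model$labels) != C) stop("labels must have length C")
  invisible(model)
}

#' @export
print.profile_model <- function(x, ...) {
  cat("Latent profile model:", x$C, "profiles,",
      length(cont_names(x$schema)), "continuous +",
      length(bin_names(x$schema)), "binary indicators\n")
  cat("weights:", paste(sprintf("%s=%.3f", x$labels, x$weights),
                        collapse = " "), "\n")
  invisible(x)
}

#' Serialize / restore a profile model
#'
#' Round-trips the full parameter set (schema, weights, means, SDs, rates,
#' labels) through a flat JSON file, stable to 1e-12.
#'
#' @param model A [profile_model].
#' @param path File path.
#' @return `read_profile_model` returns a [profile_model];
#'   `write_profile_model` returns `path` invisibly.
#' @export
write_profile_model <- function(model, path) {
  validate_profile_model(model)
  obj <- list(
    schema = list(names = model$schema$names, kinds = model$schema$kinds,
                  ranges = model$schema$ranges),
    weights = model$weights,
    cont_means = model$cont_means, cont_sds = model$cont_sds,
    bin_rates = model$bin_rates, labels = model$labels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_profile_model
#' @export
read_profile_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- indicator_schema(obj$schema$names, obj$schema$kinds,
                             as.list(obj$schema$ranges))
  profile_model(weights = obj$weights,
                cont_means = matrix(unlist(obj$cont_means), nrow = length(obj$weights)),
                cont_sds = matrix(unlist(obj$cont_sds), nrow = length(obj$weights)),
                bin_rates = matrix(unlist(obj$bin_rates), nrow = length(obj$weights)),
                schema = schema, labels = obj$labels)
}

#' Split a cohort data frame into indicator matrices
#'
#' Internal representation used by the likelihood code: a numeric matrix per
#' indicator kind plus logical observation masks (NA = unobserved). Enforces
#' the cohort-level missingness invariant (at most 2 of 9 unobserved per
#' case) and schema ranges for observed values.
#'
#' @param cohort Data frame with one row per case and the schema's indicator
#'   columns.
#' @param schema An [indicator_schema].
#' @param max_missing Maximum unobserved indicators per case (default 2).
#' @return List with `X` (continuous), `B` (binary), `obs_x`, `obs_b` masks.
#' @keywords internal
indicator_matrices <- function(cohort, schema = default_schema(),
                               max_missing = 2L) {
  cn <- cont_names(schema); bn <- bin_names(schema)
  missing_cols <- setdiff(c(cn, bn), names(cohort))
  if (length(missing_cols))
    stop("cohort is missing indicator column(s): ",
         paste(missing_cols, collapse = ", "))
  X <- as.matrix(as.data.frame(lapply(cohort[cn], as.numeric)))
  B <- as.matrix(as.data.frame(lapply(cohort[bn], as.numeric)))
  obs_x <- !is.na(X); obs_b <- !is.na(B)
  n_miss <- rowSums(!obs_x) + rowSums(!obs_b)
  if (any(n_miss > max_missing))
    stop("case(s) ", paste(utils::head(which(n_miss > max_missing), 5L),
                           collapse = ", "),
         " have more than ", max_missing, " missing indicators")
  for (k in seq_along(cn)) {
    r <- schema$ranges[[cn[k]]]
    bad <- obs_x[, k] & (X[, k] < r[1] | X[, k] > r[2])
    if (any(bad))
      stop("observed ", cn[k], " outside range [", r[1], ", ", r[2],
           "] at row(s) ", paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  bad_b <- obs_b & !(B %in% c(0, 1))
  if (any(bad_b)) stop("binary indicators must be 0/1 when observed")
  list(X = X, B = B, obs_x = obs_x, obs_b = obs_b)
}
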
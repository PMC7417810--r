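#' Univariate normal density for a continuous indicator
#'
#' The class-conditional density of a continuous indicator within a profile,
#' `f(x) = (1 / sqrt(2 pi sigma^2)) exp(-(x - mu)^2 / (2 sigma^2))`.
#'
#' @param x Score value(s).
#' @param mu Profile mean.
#' @param sigma Profile standard deviation (> 0).
#' @return Density value(s), strictly positive.
#' @export
continuous_density <- function(x, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  stats::dnorm(x, mean = mu, sd = sigma)
}

# n x C matrix of log class-conditional likelihoods, unobserved items
# marginalized by omission (exact under local independence).
log_class_lik <- function(mats, model) {
  n <- nrow(mats$X); C <- model$C
  ll <- matrix(0, n, C)
  for (k in seq_len(ncol(mats$X))) {
    ok <- mats$obs_x[, k]
    if (!any(ok)) next
    x <- mats$X[ok, k]
    for (j in seq_len(C)) {
      ll[ok, j] <- ll[ok, j] +
        stats::dnorm(x, model$cont_means[j, k], model$cont_sds[j, k], log = TRUE)
    }
  }
  for (k in seq_len(ncol(mats$B))) {
    ok <- mats$obs_b[, k]
    if (!any(ok)) next
    y <- mats$B[ok, k]
    for (j in seq_len(C)) {
      th <- model$bin_rates[j, k]
      ll[ok, j] <- ll[ok, j] + y * log(th) + (1 - y) * log1p(-th)
    }
  }
  ll
}

# accept a single indicator vector (named vector / one-row data frame / list)
as_one_row <- function(v, schema) {
  if (is.data.frame(v)) {
    df <- v
  } else {
    v <- as.list(v)
    missing_nm <- setdiff(schema$names, names(v))
    for (nm in missing_nm) v[[nm]] <- NA_real_
    df <- as.data.frame(v[schema$names])
  }
  if (nrow(df) != 1L) stop("expected a single indicator vector")
  df
}

#' Class-conditional likelihood of one case under one profile
#'
#' Product over the observed indicators of the Gaussian density (continuous
#' items) and the Bernoulli mass (binary items), assuming local independence
#' given the profile. Unobserved indicators (at most two) are marginalized
#' by omitting their factors.
#'
#' @param v Named vector, list or one-row data frame of indicator values;
#'   `NA` marks an unobserved indicator.
#' @param model A [profile_model].
#' @param j Profile index in `1..C`.
#' @return Non-negative likelihood value.
#' @export
class_conditional_likelihood <- function(v, model, j) {
  validate_profile_model(model)
  if (j < 1L || j > model$C) stop("profile index j out of range")
  mats <- indicator_matrices(as_one_row(v, model$schema), model$schema)
  if (!any(mats$obs_x) && !any(mats$obs_b))
    stop("all indicators missing: cannot evaluate likelihood")
  exp(log_class_lik(mats, model)[1, j])
}

alloc_from_log <- function(ll, weights, labels) {
  n <- nrow(ll); C <- ncol(ll)
  a <- sweep(ll, 2, log(weights), "+")
  if (any(!is.finite(apply(a, 1, max))))
    stop("case outside model support: all class likelihoods are zero for row(s) ",
         paste(utils::head(which(!is.finite(apply(a, 1, max))), 5L), collapse = ", "))
  mx <- apply(a, 1, max)
  p <- exp(a - mx)
  p <- p / rowSums(p)
  primary <- max.col(p, ties.method = "first")
  if (C >= 2L) {
    p2 <- p
    p2[cbind(seq_len(n), primary)] <- -Inf
    secondary <- max.col(p2, ties.method = "first")
  } else {
    secondary <- rep(NA_integer_, n)
  }
  structure(list(probs = p, primary = primary, secondary = secondary,
                 max_prob = p[cbind(seq_len(n), primary)],
                 labels = labels),
            class = "profile_allocation")
}

#' Posterior profile membership for one case
#'
#' Bayes-rule posterior `P(X = j | Y = y)` proportional to
#' `pi_j * L_j(y)`, evaluated with log-sum-exp stabilization. The primary
#' profile is the posterior argmax and the secondary profile the runner-up
#' (ties broken toward the lower profile index).
#'
#' @inheritParams class_conditional_likelihood
#' @return List with `probs` (length-`C`, sums to one), `primary`,
#'   `secondary` (NA when `C == 1`), `max_prob`.
#' @export
posterior_probabilities <- function(v, model) {
  validate_profile_model(model)
  mats <- indicator_matrices(as_one_row(v, model$schema), model$schema)
  a <- alloc_from_log(log_class_lik(mats, model), model$weights, model$labels)
  list(probs = as.numeric(a$probs[1, ]), primary = a$primary[1],
       secondary = a$secondary[1], max_prob = a$max_prob[1])
}

#' Allocate a cohort to latent profiles
#'
#' Applies [posterior_probabilities()] to every case, order-preserving and
#' deterministic. Each case is allocated to the profile with the highest
#' posterior membership probability; the profile with the second-highest
#' probability is recorded as the secondary profile.
#'
#' @param cohort Data frame with the schema's indicator columns (NA =
#'   unobserved, at most two per case).
#' @param model A [profile_model].
#' @return A `profile_allocation`: list with `probs` (n x C matrix),
#'   `primary`, `secondary`, `max_prob`, `labels`.
#' @export
allocate <- function(cohort, model) {
  validate_profile_model(model)
  if (nrow(cohort) == 0L) stop("cohort is empty")
  mats <- indicator_matrices(cohort, model$schema)
  tryCatch(
    alloc_from_log(log_class_lik(mats, model), model$weights, model$labels),
    error = function(e) stop("allocation failed: ", conditionMessage(e),
                             call. = FALSE))
}

#' Total observed-data log-likelihood of a cohort
#'
#' `sum_i log sum_j pi_j L_j(y_i)`, computed with log-sum-exp.
#'
#' @inheritParams allocate
#' @return Finite scalar log-likelihood.
#' @export
log_likelihood <- function(cohort, model) {
  validate_profile_model(model)
  mats <- indicator_matrices(cohort, model$schema)
  sum(row_logsumexp(sweep(log_class_lik(mats, model), 2,
                          log(model$weights), "+")))
}

row_logsumexp <- function(a) {
  mx <- apply(a, 1, max)
  mx + log(rowSums(exp(a - mx)))
}

# one EM run from given responsibilities; returns model + trace
em_run <- function(mats, C, resp, schema, tol, max_iter) {
  n <- nrow(mats$X)
  trace <- numeric(0)
  model <- NULL
  warnings <- character(0)
  for (it in seq_len(max_iter)) {
    # M-step
    w <- colSums(resp) / n
    w <- pmax(w, 1e-8); w <- w / sum(w)
    nc <- ncol(mats$X); nb <- ncol(mats$B)
    mu <- sg <- matrix(0, C, nc); th <- matrix(0, C, nb)
    for (k in seq_len(nc)) {
      ok <- mats$obs_x[, k]
      x <- mats$X[ok, k]; r <- resp[ok, , drop = FALSE]
      rs <- colSums(r)
      mu[, k] <- colSums(r * x) / rs
      v <- colSums(r * (outer(x, mu[, k], "-")^2)) / rs
      if (any(v < .VAR_FLOOR)) {
        warnings <- unique(c(warnings, paste0(
          "variance floor engaged for continuous indicator '",
          cont_names(schema)[k], "'")))
      }
      sg[, k] <- sqrt(pmax(v, .VAR_FLOOR))
    }
    for (k in seq_len(nb)) {
      ok <- mats$obs_b[, k]
      y <- mats$B[ok, k]; r <- resp[ok, , drop = FALSE]
      th[, k] <- colSums(r * y) / colSums(r)
    }
    th <- pmin(pmax(th, .RATE_CLIP), 1 - .RATE_CLIP)
    model <- profile_model(w, mu, sg, th, schema = schema)
    # E-step
    a <- sweep(log_class_lik(mats, model), 2, log(w), "+")
    lse <- row_logsumexp(a)
    trace <- c(trace, sum(lse))
    resp <- exp(a - lse)
    if (it >= 2L) {
      prev <- trace[it - 1L]
      if (abs(trace[it] - prev) <= tol * (abs(prev) + 1e-12)) break
    }
  }
  list(model = model, trace = trace, loglik = trace[length(trace)],
       resp = resp, warnings = warnings)
}

init_resp <- function(mats, C, n) {
  # k-means-style seed on all standardized indicators (missing -> column
  # mean), softened with uniform noise for diversity across restarts
  X <- cbind(mats$X, mats$B)
  obs <- cbind(mats$obs_x, mats$obs_b)
  for (k in seq_len(ncol(X))) {
    m <- mean(X[obs[, k], k])
    X[!obs[, k], k] <- m
  }
  Z <- scale(X)
  Z[, !is.finite(apply(Z, 2, stats::sd)) | is.na(apply(Z, 2, stats::sd))] <- 0
  Z[!is.finite(Z)] <- 0
  part <- tryCatch(
    stats::kmeans(Z, centers = min(C, nrow(unique(Z))), nstart = 1,
                  iter.max = 20)$cluster,
    error = function(e) sample.int(C, n, replace = TRUE))
  if (max(part) < C) part <- sample.int(C, n, replace = TRUE)
  resp <- matrix(stats::runif(n * C, 0, 1), n, C)
  resp[cbind(seq_len(n), part)] <- resp[cbind(seq_len(n), part)] + 4
  resp / rowSums(resp)
}

#' Fit a latent profile model by EM
#'
#' Maximum-likelihood estimation of the mixed Gaussian/Bernoulli mixture by
#' expectation-maximization with multiple restarts. Each restart is seeded
#' from a k-means partition of the standardized continuous indicators plus
#' random perturbation; the highest-log-likelihood solution is returned.
#' The observed-data log-likelihood is non-decreasing within each run (up to
#' the variance floor), sigma is floored at `sqrt(1e-4)` and Bernoulli rates
#' clipped to `[1e-6, 1 - 1e-6]` to guard against degenerate components.
#'
#' @inheritParams allocate
#' @param C Number of profiles (>= 1); the cohort must hold at least `10 * C`
#'   cases and more distinct cases than `C`.
#' @param seed Integer seed governing all restarts.
#' @param n_starts Number of EM restarts (default 20).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-7).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param schema Indicator schema (default [default_schema()]).
#' @return A [profile_model] with attributes `logLik`, `trace` (per-iteration
#'   log-likelihood of the winning run), `n_iter`, `n_starts`, and
#'   `warnings` (character, e.g. variance-floor records).
#' @export
fit_em <- function(cohort, C, seed = 1L, n_starts = 20L, tol = 1e-7,
                   max_iter = 500L, schema = default_schema()) {
  if (C < 1L) stop("C must be >= 1")
  if (nrow(cohort) < 10 * C)
    stop("cohort too small: need at least 10*C = ", 10 * C, " cases")
  mats <- indicator_matrices(cohort, schema)
  n <- nrow(mats$X)
  key <- apply(cbind(mats$X, mats$B), 1, paste, collapse = "\r")
  if (length(unique(key)) < C)
    stop("C exceeds the number of distinct cases (",
         length(unique(key)), ")")
  for (k in seq_len(ncol(mats$X))) {
    xk <- mats$X[mats$obs_x[, k], k]
    if (length(unique(xk)) == 1L)
      warning("continuous indicator '", cont_names(schema)[k],
              "' is constant; variance floor will apply")
  }
  best <- NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (s in seq_len(n_starts)) {
    resp <- if (C == 1L) matrix(1, n, 1) else init_resp(mats, C, n)
    run <- em_run(mats, C, resp, schema, tol, max_iter)
    if (is.null(best) || run$loglik > best$loglik) best <- run
    if (C == 1L) break  # single-component MLE is deterministic
  }
  fit <- best$model
  attr(fit, "logLik") <- best$loglik
  attr(fit, "trace") <- best$trace
  attr(fit, "n_iter") <- length(best$trace)
  attr(fit, "n_starts") <- n_starts
  attr(fit, "warnings") <- best$warnings
  for (w in best$warnings) warning(w, call. = FALSE)
  fit
}

#' Model-fit statistics over a range of profile counts
#'
#' Fits the mixture for each candidate `C` and reports log-likelihood,
#' parameter count `(C - 1) + C * (2 * n_cont + n_bin)`, AIC, BIC, and the
#' relative entropy `1 - sum_i sum_j (-p_ij log p_ij) / (n log C)`
#' (1 for `C = 1` by convention: no classification uncertainty).
#'
#' @inheritParams fit_em
#' @param C_range Integer vector of candidate profile counts.
#' @param schema Indicator schema (default [default_schema()]).
#' @param ... Passed to [fit_em()] (`n_starts`, `tol`, `max_iter`).
#' @return Data frame with one row per `C`: `C`, `loglik`, `n_par`, `AIC`,
#'   `BIC`, `entropy`. Fitted models attached as attribute `fits`.
#' @export
model_selection <- function(cohort, C_range, seed = 1L,
                            schema = default_schema(), ...) {
  if (!length(C_range)) stop("C_range must be non-empty")
  n <- nrow(cohort)
  nc <- length(cont_names(schema)); nb <- length(bin_names(schema))
  rows <- vector("list", length(C_range))
  fits <- vector("list", length(C_range))
  for (i in seq_along(C_range)) {
    C <- C_range[i]
    fit <- fit_em(cohort, C, seed = seed + i - 1L, ...)
    ll <- attr(fit, "logLik")
    k <- (C - 1L) + C * (2L * nc + nb)
    ent <- if (C == 1L) 1 else {
      p <- allocate(cohort, fit)$probs
      plogp <- ifelse(p > 0, -p * log(p), 0)
      1 - sum(plogp) / (n * log(C))
    }
    rows[[i]] <- data.frame(C = C, loglik = ll, n_par = k,
                            AIC = -2 * ll + 2 * k,
                            BIC = -2 * ll + k * log(n),
                            entropy = ent)
    fits[[i]] <- fit
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}

perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- perms(k - 1L)
  out <- do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
  dimnames(out) <- NULL
  out
}

#' Align fitted profile labels to a reference model
#'
#' Resolves label switching: permutes the fitted model's profiles to
#' minimize the total squared distance between continuous-mean rows of the
#' fitted and reference models (exhaustive optimal assignment, `C <= 8`).
#'
#' @param fitted,reference [profile_model]s with equal `C` and schema.
#' @return The fitted model with profiles permuted; labels taken from the
#'   reference. Attribute `permutation` gives the applied ordering
#'   (fitted row used for each reference slot).
#' @export
align_labels <- function(fitted, reference) {
  if (fitted$C != reference$C) stop("models have unequal C")
  if (!identical(fitted$schema$names, reference$schema$names))
    stop("models have different schemas")
  C <- fitted$C
  if (C > 8L) stop("exhaustive alignment supported for C <= 8")
  D <- matrix(0, C, C)  # D[j, k]: cost of placing fitted j in reference slot k
  for (j in seq_len(C)) for (k in seq_len(C))
    D[j, k] <- sum((fitted$cont_means[j, ] - reference$cont_means[k, ])^2)
  P <- perms(C)
  costs <- apply(P, 1, function(pr) sum(D[cbind(pr, seq_len(C))]))
  pr <- P[which.min(costs), ]
  out <- profile_model(fitted$weights[pr],
                       fitted$cont_means[pr, , drop = FALSE],
                       fitted$cont_sds[pr, , drop = FALSE],
                       fitted$bin_rates[pr, , drop = FALSE],
                       schema = fitted$schema, labels = reference$labels)
  attr(out, "permutation") <- pr
  for (a in c("logLik", "trace", "n_iter"))
    attr(out, a) <- attr(fitted, a)
  out
}
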
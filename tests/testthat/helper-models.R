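# shared fixtures: small hand-built models and cohorts

cont_names <- function(s) lpaoutcomes:::cont_names(s)
bin_names <- function(s) lpaoutcomes:::bin_names(s)

# a tiny 2-profile model on the default 9-indicator schema, strongly
# separated (>= 3 within-profile SDs on every continuous item)
two_profile_model <- function() {
  profile_model(
    weights = c(0.4, 0.6),
    cont_means = rbind(c(6, 5, 8, 30), c(20, 17, 30, 60)),
    cont_sds = matrix(rep(c(1.5, 1.2, 2, 2.5), each = 2), 2),
    bin_rates = rbind(c(.15, .6, .2, .1, .2), c(.85, .7, .8, .7, .5)),
    labels = c("A", "B"))
}

# sample a cohort from an arbitrary profile_model (independent of the
# package generator; integer rounding/clipping optional)
sample_from_model <- function(model, n, seed, round_scores = FALSE) {
  set.seed(seed)
  z <- sample.int(model$C, n, replace = TRUE, prob = model$weights)
  out <- data.frame(row.names = seq_len(n))
  cn <- cont_names(model$schema)
  for (k in seq_along(cn)) {
    x <- rnorm(n, model$cont_means[z, k], model$cont_sds[z, k])
    r <- model$schema$ranges[[cn[k]]]
    if (round_scores) x <- round(x)
    out[[cn[k]]] <- pmin(pmax(x, r[1]), r[2])
  }
  bn <- bin_names(model$schema)
  for (k in seq_along(bn))
    out[[bn[k]]] <- as.numeric(runif(n) < model$bin_rates[z, k])
  attr(out, "true_class") <- z
  out
}

# random valid model on the default schema, for property tests
random_model <- function(C, seed) {
  set.seed(seed)
  w <- runif(C, 0.5, 2); w <- w / sum(w)
  s <- default_schema()
  nc <- 4L; nb <- 5L
  mu <- sapply(seq_len(nc), function(k) {
    r <- s$ranges[[cont_names(s)[k]]]
    runif(C, r[1] + 1, r[2] - 1)
  })
  profile_model(w, matrix(mu, C), matrix(runif(C * nc, 1, 6), C),
                matrix(runif(C * nb, 0.05, 0.95), C))
}

# random indicator row inside schema ranges, with optional missing items
random_case <- function(seed, n_missing = 0L) {
  set.seed(seed)
  s <- default_schema()
  v <- list()
  for (nm in cont_names(s)) {
    r <- s$ranges[[nm]]
    v[[nm]] <- runif(1, r[1], r[2])
  }
  for (nm in bin_names(s)) v[[nm]] <- as.numeric(runif(1) < 0.5)
  if (n_missing > 0) {
    drop <- sample(s$names, n_missing)
    for (nm in drop) v[[nm]] <- NA_real_
  }
  as.data.frame(v)
}

indicator_matrices_public <- function(...) lpaoutcomes:::indicator_matrices(...)
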
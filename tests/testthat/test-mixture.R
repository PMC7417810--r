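test_that("continuous_density matches the normal density and integrates to 1", {
  expect_equal(continuous_density(0, 0, 1), 1 / sqrt(2 * pi),
               tolerance = 1e-7)
  for (s in c(0.5, 2, 5))
    expect_equal(continuous_density(3, 3, s), 1 / (s * sqrt(2 * pi)),
                 tolerance = 1e-12)
  # quadrature oracle: the density must integrate to 1 over mu +/- 10 sd
  q <- stats::integrate(continuous_density, 10 - 50, 10 + 50,
                        mu = 10, sigma = 5, rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-8)
  expect_equal(continuous_density(13.8, 10, 5),
               exp(-(13.8 - 10)^2 / (2 * 25)) / (5 * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_error(continuous_density(0, 0, 0), "positive")
})

test_that("class_conditional_likelihood is the local-independence product", {
  # single binary indicator: Bernoulli mass
  m1 <- random_model(2, seed = 10)
  v <- random_case(11)
  # brute-force straight-line product oracle over the 9 indicators
  for (j in 1:2) {
    oracle <- m1$weights[j] / m1$weights[j]  # 1
    s <- default_schema()
    for (k in 1:4)
      oracle <- oracle * dnorm(v[[cont_names(s)[k]]],
                               m1$cont_means[j, k], m1$cont_sds[j, k])
    for (k in 1:5) {
      y <- v[[bin_names(s)[k]]]
      th <- m1$bin_rates[j, k]
      oracle <- oracle * th^y * (1 - th)^(1 - y)
    }
    expect_equal(class_conditional_likelihood(v, m1, j), oracle,
                 tolerance = 1e-12)
  }
  # missing indicators marginalized by omission
  v2 <- v; v2$wsas <- NA_real_; v2$phobia <- NA_real_
  l_full <- class_conditional_likelihood(v, m1, 1)
  l_marg <- class_conditional_likelihood(v2, m1, 1)
  th <- m1$bin_rates[1, 1]
  expect_equal(l_marg,
               l_full / dnorm(v$wsas, m1$cont_means[1, 3], m1$cont_sds[1, 3]) /
                 (th^v$phobia * (1 - th)^(1 - v$phobia)),
               tolerance = 1e-10)
  expect_error(class_conditional_likelihood(v, m1, 3), "out of range")
})

test_that("posterior probabilities follow Bayes rule", {
  # identical profiles: posterior equals the prior for any input
  m <- two_profile_model()
  m_same <- profile_model(c(0.3, 0.7),
                          m$cont_means[c(1, 1), ], m$cont_sds[c(1, 1), ],
                          m$bin_rates[c(1, 1), ])
  for (s in 1:3) {
    p <- posterior_probabilities(random_case(s), m_same)
    expect_equal(p$probs, c(0.3, 0.7), tolerance = 1e-12)
    expect_equal(p$primary, 2L)
    expect_equal(p$secondary, 1L)
  }
})

test_that("posterior vectors sum to 1 and match the naive Bayes oracle", {
  for (s in 1:20) {
    C <- sample(2:8, 1)
    m <- random_model(C, seed = 100 + s)
    v <- random_case(200 + s, n_missing = sample(0:2, 1))
    p <- posterior_probabilities(v, m)
    expect_equal(sum(p$probs), 1, tolerance = 1e-9)
    # naive, non-stabilized evaluation
    lik <- vapply(seq_len(C), function(j)
      class_conditional_likelihood(v, m, j), numeric(1))
    naive <- m$weights * lik / sum(m$weights * lik)
    if (all(is.finite(naive)))
      expect_equal(p$probs, naive, tolerance = 1e-10)
    expect_equal(p$primary, which.max(p$probs))
    expect_false(p$secondary == p$primary)
    expect_equal(p$probs[p$secondary],
                 max(p$probs[-p$primary]))
  }
})

test_that("single-profile posteriors are degenerate", {
  m <- random_model(1, seed = 5)
  p <- posterior_probabilities(random_case(6), m)
  expect_equal(p$probs, 1)
  expect_equal(p$primary, 1L)
  expect_true(is.na(p$secondary))
})

test_that("allocate is a pure per-case mapping and permutation-equivariant", {
  m <- random_model(4, seed = 31)
  coh <- do.call(rbind, lapply(1:15, random_case))
  al <- allocate(coh, m)
  for (i in c(1, 7, 15)) {
    p <- posterior_probabilities(coh[i, ], m)
    expect_equal(as.numeric(al$probs[i, ]), p$probs, tolerance = 1e-12)
    expect_equal(al$primary[i], p$primary)
    expect_equal(al$secondary[i], p$secondary)
  }
  # permute model profiles: primary/secondary permute identically
  pr <- c(3, 1, 4, 2)
  mp <- profile_model(m$weights[pr], m$cont_means[pr, ], m$cont_sds[pr, ],
                      m$bin_rates[pr, ], labels = m$labels[pr])
  alp <- allocate(coh, mp)
  inv <- order(pr)
  expect_equal(alp$primary, inv[al$primary])
  expect_equal(alp$secondary, inv[al$secondary])
})

test_that("well-separated two-profile cohorts allocate to the truth", {
  m <- two_profile_model()
  coh <- sample_from_model(m, 2000, seed = 17)
  al <- allocate(coh, m)
  expect_gte(mean(al$primary == attr(coh, "true_class")), 0.99)
})

test_that("log_likelihood is additive and matches naive summation", {
  m <- random_model(3, seed = 41)
  coh <- do.call(rbind, lapply(1:8, function(s) random_case(300 + s)))
  ll <- log_likelihood(coh, m)
  # naive oracle without log-sum-exp
  naive <- sum(vapply(seq_len(nrow(coh)), function(i) {
    lik <- vapply(1:3, function(j)
      class_conditional_likelihood(coh[i, ], m, j), numeric(1))
    log(sum(m$weights * lik))
  }, numeric(1)))
  expect_equal(ll, naive, tolerance = 1e-10)
  expect_equal(log_likelihood(rbind(coh, coh), m), 2 * ll,
               tolerance = 1e-10)
})

test_that("C=1 EM fit equals closed-form sample moments", {
  m <- two_profile_model()
  coh <- sample_from_model(m, 120, seed = 53)
  fit <- fit_em(coh, 1, seed = 1)
  s <- default_schema()
  for (k in 1:4) {
    x <- coh[[cont_names(s)[k]]]
    expect_equal(fit$cont_means[1, k], mean(x), tolerance = 1e-8)
    expect_equal(fit$cont_sds[1, k],
                 sqrt(mean((x - mean(x))^2)), tolerance = 1e-8)
  }
  for (k in 1:5)
    expect_equal(fit$bin_rates[1, k], mean(coh[[bin_names(s)[k]]]),
                 tolerance = 1e-8)
  expect_equal(fit$weights, 1)
})

test_that("EM recovers a well-separated two-profile generator", {
  m <- two_profile_model()   # >= 3 SD separation on continuous items
  coh <- sample_from_model(m, 2000, seed = 61)
  fit <- fit_em(coh, 2, seed = 7, n_starts = 5)
  alg <- align_labels(fit, m)
  expect_lt(max(abs(alg$cont_means - m$cont_means)), 0.15)
  expect_lt(max(abs(alg$bin_rates - m$bin_rates)), 0.05)
  expect_lt(max(abs(alg$weights - m$weights)), 0.03)
  # EM guarantee: monotone non-decreasing log-likelihood trace
  tr <- attr(fit, "trace")
  expect_true(all(diff(tr) >= -1e-8 * pmax(1, abs(tr[-1]))))
})

test_that("EM log-likelihood trace is monotone across seeds and C", {
  m <- two_profile_model()
  coh <- sample_from_model(m, 300, seed = 71)
  for (spec in list(c(2, 1), c(3, 2), c(4, 3))) {
    fit <- fit_em(coh, spec[1], seed = spec[2], n_starts = 2,
                  max_iter = 80)
    tr <- attr(fit, "trace")
    expect_true(all(diff(tr) >= -1e-8 * pmax(1, abs(tr[-1]))))
  }
})

test_that("EM guards degenerate inputs", {
  m <- two_profile_model()
  coh <- sample_from_model(m, 60, seed = 81)
  coh$wsas <- 12  # constant continuous indicator
  w <- capture_warnings(fit_em(coh, 2, seed = 1, n_starts = 1,
                               max_iter = 40))
  expect_true(any(grepl("wsas", w)))
  expect_true(any(grepl("variance floor", w)))
  tiny <- sample_from_model(m, 25, seed = 82)[rep(1, 25), ]
  expect_error(fit_em(tiny, 2, seed = 1), "distinct")
  expect_error(fit_em(coh[1:15, ], 2, seed = 1), "cohort too small")
})

test_that("model_selection reports the stated statistics", {
  m <- two_profile_model()
  coh <- sample_from_model(m, 400, seed = 91)
  tab <- model_selection(coh, 1:3, seed = 3, n_starts = 3, max_iter = 150)
  # parameter count: (C-1) + C*(2*4 + 5)
  expect_equal(tab$n_par, (1:3 - 1) + (1:3) * 13)
  expect_equal(tab$n_par[tab$C == 1], 13)
  expect_equal(tab$entropy[tab$C == 1], 1)
  expect_true(all(tab$entropy <= 1 + 1e-12))
  expect_equal(tab$AIC, -2 * tab$loglik + 2 * tab$n_par)
  expect_equal(tab$BIC, -2 * tab$loglik + tab$n_par * log(400))
  # strong 2-profile structure: BIC minimized at C=2
  expect_equal(tab$C[which.min(tab$BIC)], 2)
})

test_that("parameter count arithmetic for the deployed configuration", {
  # C=8 with 4 continuous + 5 binary indicators
  expect_equal((8 - 1) + 8 * (2 * 4 + 5), 111)
})

test_that("align_labels finds the optimal assignment", {
  ref <- random_model(6, seed = 101)
  # identity
  a <- align_labels(ref, ref)
  expect_equal(attr(a, "permutation"), 1:6)
  # a known permutation is recovered exactly
  pr <- c(4, 6, 1, 3, 2, 5)
  fitted <- profile_model(ref$weights[pr], ref$cont_means[pr, ],
                          ref$cont_sds[pr, ], ref$bin_rates[pr, ])
  a <- align_labels(fitted, ref)
  expect_equal(a$cont_means, ref$cont_means, ignore_attr = TRUE)
  expect_equal(a$weights, ref$weights)
  # with noise, the assignment cost equals the exhaustive minimum computed
  # by an independent straight-line search
  set.seed(7)
  noisy <- profile_model(ref$weights[pr],
                         ref$cont_means[pr, ] + rnorm(24, 0, 0.3),
                         ref$cont_sds[pr, ], ref$bin_rates[pr, ])
  a <- align_labels(noisy, ref)
  paste_cost <- function(ordering)
    sum((noisy$cont_means[ordering, ] - ref$cont_means)^2)
  enumerate <- function(avail) {
    if (length(avail) == 1L) return(list(avail))
    out <- list()
    for (x in avail)
      for (rest in enumerate(setdiff(avail, x)))
        out[[length(out) + 1L]] <- c(x, rest)
    out
  }
  best <- min(vapply(enumerate(1:6), paste_cost, numeric(1)))
  expect_equal(paste_cost(attr(a, "permutation")), best, tolerance = 1e-12)
  expect_error(align_labels(random_model(3, 1), ref), "unequal C")
})
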
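test_that("AIC arithmetic", {
  expect_equal(compute_aic(0), 6)
  expect_equal(compute_aic(10), 26)
  expect_equal(compute_aic(80 * log(2)), 6 + 160 * log(2))
  expect_error(compute_aic(-1), "nll")
})

test_that("MLE beats coin flipping on random choices and flags inflexibility", {
  # data simulated with beta = 0: the coin-flip NLL n*log(2) upper-bounds
  # the optimum (finite samples allow slight noise fitting)
  tr <- fixture_subject(beta = 0, seed = 5)
  fit <- fit_mle(tr, "linear", n_starts = 6, seed = 2)
  expect_lte(fit$nll, 80 * log(2) + 1e-6)
  expect_false(fit$inflexible)
  # all-identical choices are fit but flagged, not raised
  tr$choice <- 1L
  flag <- fit_mle(tr, "linear", n_starts = 4, seed = 2)
  expect_true(flag$inflexible)
  expect_false(flag$converged)
  expect_error(fit_mle(tr[0, ], "linear"), "empty")
})

test_that("optimizer matches a dense grid search on a 20-trial fixture", {
  tr <- fixture_trials_20()
  fit <- fit_mle(tr, "linear", n_starts = 8, seed = 3)
  ks <- seq(0, 5, length.out = 25)
  betas <- seq(0, 30, length.out = 25)
  cs <- seq(-10, 10, length.out = 25)
  best <- Inf
  for (k in ks) for (b in betas) {
    sv <- tr$incentive_level - k * tr$effort_level
    for (cc in cs) {
      p <- pmin(pmax(stats::plogis(b * (sv + cc)), 1e-12), 1 - 1e-12)
      nll <- -sum(tr$choice * log(p) + (1 - tr$choice) * log(1 - p))
      if (nll < best) best <- nll
    }
  }
  expect_lte(fit$nll, best + 1e-3)
})

test_that("single-agent k is recovered across replicate datasets", {
  # agent (linear, k = 0.5, beta = 3, c = 0), 80 trials per replicate
  khat <- vapply(1:60, function(i) {
    tr <- fixture_subject("linear", k = 0.5, beta = 3, c = 0, seed = 100 + i)
    fit_mle(tr, "linear", n_starts = 5, seed = i)$k
  }, numeric(1))
  expect_lt(abs(mean(khat) - 0.5), 0.15)
})

test_that("fitting is invariant to trial order", {
  tr <- fixture_subject(seed = 9)
  fit1 <- fit_mle(tr, "parabolic", n_starts = 5, seed = 4)
  perm <- withr::with_seed(1, tr[sample.int(nrow(tr)), ])
  fit2 <- fit_mle(perm, "parabolic", n_starts = 5, seed = 4)
  expect_equal(fit1$nll, fit2$nll, tolerance = 1e-6)
  expect_equal(fit1$k, fit2$k, tolerance = 1e-3)
})

test_that("empirical priors are the pooled mean and ridged covariance", {
  same <- tibble::tibble(family = "linear", stage = "mle",
                         k = rep(0.5, 4), beta = rep(3, 4), c = rep(-1, 4))
  pr <- estimate_empirical_prior(same, "linear", ridge = 1e-4)
  expect_equal(unname(pr$mu), c(0.5, 3, -1))
  expect_equal(pr$sigma, diag(1e-4, 3), ignore_attr = TRUE)
  two <- tibble::tibble(family = "linear", stage = "mle",
                        k = c(0, 1), beta = c(2, 4), c = c(-2, 0))
  expect_equal(unname(estimate_empirical_prior(two, "linear")$mu),
               c(0.5, 3, -1))
  expect_error(estimate_empirical_prior(same[1, ], "linear"), "at least 2")
  # random table matches the direct formula
  tab <- withr::with_seed(8, tibble::tibble(
    family = "exponential", stage = "mle",
    k = runif(10), beta = runif(10, 0, 5), c = rnorm(10)
  ))
  pr2 <- estimate_empirical_prior(tab, "exponential", ridge = 1e-4)
  theta <- cbind(tab$k, tab$beta, tab$c)
  expect_equal(unname(pr2$mu), unname(colMeans(theta)))
  expect_equal(unname(pr2$sigma), unname(cov(theta) + diag(1e-4, 3)))
})

test_that("MAP reduces to MLE under a vague prior and shrinks otherwise", {
  tr <- fixture_subject("linear", k = 0.7, beta = 4, c = -1, seed = 13)
  mle <- fit_mle(tr, "linear", n_starts = 6, seed = 2)
  vague <- structure(list(family = "linear", mu = c(k = 0.5, beta = 3, c = 0),
                          sigma = diag(1e6, 3), ridge = 0),
                     class = "empirical_prior")
  map_v <- fit_map(tr, "linear", vague, n_starts = 6, seed = 2)
  expect_equal(map_v$k, mle$k, tolerance = 1e-2)
  expect_equal(map_v$nll, mle$nll, tolerance = 1e-4)
  # informative prior: MAP is never farther from mu (Mahalanobis) than MLE
  mu <- c(0.2, 2, 0)
  sigma <- diag(c(0.05, 1, 1))
  inf <- structure(list(family = "linear", mu = mu, sigma = sigma,
                        ridge = 0), class = "empirical_prior")
  map_i <- fit_map(tr, "linear", inf, n_starts = 6, seed = 2)
  d <- function(th) sqrt(mahalanobis(matrix(th, 1), mu, sigma))
  expect_lte(d(c(map_i$k, map_i$beta, map_i$c)),
             d(c(mle$k, mle$beta, mle$c)) + 1e-6)
})

test_that("a flat likelihood direction collapses onto the prior mean", {
  # beta pinned at 0 makes the likelihood independent of k, so the MAP
  # estimate of k must equal mu_k
  tr <- fixture_subject(beta = 0, seed = 21)
  prior <- structure(list(family = "linear",
                          mu = c(k = 0.4, beta = 0, c = 0),
                          sigma = diag(c(0.1, 1e-6, 0.1)), ridge = 0),
                     class = "empirical_prior")
  map <- fit_map(tr, "linear", prior, n_starts = 6, seed = 2)
  expect_equal(map$k, 0.4, tolerance = 0.05)
})

test_that("the cohort driver runs both stages with pooled priors", {
  co <- generate_cohort(cohort_spec(n_per_group = 3, inflexible_rate = 0,
                                    seed = 6))
  out <- fit_cohort(co$trials, families = c("linear", "hyperbolic"),
                    n_starts = 4, seed = 2)
  expect_setequal(unique(out$fits$stage), c("mle", "map"))
  expect_equal(nrow(out$fits), 6 * 2 * 2)
  expect_named(out$priors, c("linear", "hyperbolic"))
  # deterministic under the root seed
  out2 <- fit_cohort(co$trials, families = c("linear", "hyperbolic"),
                     n_starts = 4, seed = 2)
  expect_equal(out$fits, out2$fits)
})
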
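test_that("log rates add intercept and the three effects along the diagonal", {
  g <- lexis_grid()
  p0 <- apc_parameters(-9, rep(0, 10), rep(0, 6), rep(0, 15))
  expect_equal(apc_log_rate(p0, g, 3, 2), -9)

  pars <- apc_parameters(-9, seq(0.1, 1, by = 0.1), seq(-0.1, 0.4, by = 0.1),
                         seq(-0.7, 0.7, by = 0.1))
  expect_equal(apc_log_rate(pars, g, 4, 2),
               -9 + pars$alpha[4] + pars$beta[2] + pars$gamma[8])

  eta <- apc_log_rate(pars, g)
  for (a in 1:10) for (p in 1:6)   # loop oracle over the full grid
    expect_equal(eta[a, p], pars$mu + pars$alpha[a] + pars$beta[p] +
                   pars$gamma[cohort_index(a, p, g)])
})

test_that("log likelihood equals cell-wise Poisson pmf summation", {
  g <- lexis_grid(n_age = 3, n_period = 3)
  set.seed(5)
  d <- matrix(rpois(9, 8), 3, 3)
  py <- matrix(runif(9, 1e3, 1e5), 3, 3)
  cnt <- stratum_counts(g, "male", "low", d, py)
  pars <- random_params(g, sd = 0.4)
  eta <- apc_log_rate(pars, g)
  oracle <- sum(dpois(d, py * exp(eta), log = TRUE))
  expect_equal(apc_loglik(pars, cnt), oracle, tolerance = 1e-10)

  # zero counts: sum of -N*lambda
  cnt0 <- stratum_counts(g, "male", "low", matrix(0L, 3, 3), py)
  expect_equal(apc_loglik(pars, cnt0), -sum(py * exp(eta)), tolerance = 1e-10)

  # single cell D=3, N=1000, lambda=0.003
  g1 <- lexis_grid(n_age = 2, n_period = 2)
  cnt1 <- stratum_counts(g1, "male", "low",
                         matrix(c(3L, 0L, 0L, 0L), 2, 2),
                         matrix(c(1000, 1e-6, 1e-6, 1e-6), 2, 2))
  mu <- log(0.003)
  p1 <- apc_parameters(mu, rep(0, 2), rep(0, 2), rep(0, 3))
  contrib_others <- -sum(1e-6 * 0.003 * c(1, 1, 1))
  expect_equal(apc_loglik(p1, cnt1), dpois(3, 3, log = TRUE) + contrib_others,
               tolerance = 1e-9)
})

test_that("RW2 log prior equals the second-difference Gaussian density", {
  # perfectly linear effects: all second differences zero
  lin <- seq(0.5, 2.3, by = 0.2)
  s2 <- 0.3
  expect_equal(rw2_logprior(lin, s2),
               (length(lin) - 2) * dnorm(0, 0, sqrt(s2), log = TRUE))
  # length-3 (0, 0, 1): one standard-normal evaluation at 1
  expect_equal(rw2_logprior(c(0, 0, 1), 1), dnorm(1, log = TRUE))

  # oracle: density of the (K-2)-dim Gaussian of D2 %*% x, covariance s2*I
  set.seed(13)
  for (K in 3:20) {
    x <- rnorm(K, 0, 2)
    s2 <- runif(1, 0.01, 2)
    D2 <- matrix(0, K - 2, K)
    for (j in seq_len(K - 2)) D2[j, j:(j + 2)] <- c(1, -2, 1)
    d2 <- as.vector(D2 %*% x)
    Sigma <- diag(s2, K - 2)
    oracle <- -0.5 * (K - 2) * log(2 * pi) - 0.5 * determinant(Sigma)$modulus[1] -
      0.5 * t(d2) %*% solve(Sigma, d2)
    expect_equal(rw2_logprior(x, s2), as.numeric(oracle), tolerance = 1e-10)
  }
  expect_error(rw2_logprior(c(1, 2, 3), 0), "positive")
  expect_error(rw2_logprior(c(1, 2), 1), "at least 3")
})

test_that("constraint transform pins references and preserves fitted rates", {
  g <- lexis_grid()
  spec <- apc_model_spec(g)

  # already-constrained state passes through unchanged
  pars <- random_params(g)
  c1 <- apply_constraints(pars, spec)
  c2 <- apply_constraints(c1, spec)
  expect_equal(c1$mu, c2$mu)
  expect_equal(c1$alpha, c2$alpha)
  expect_equal(c1$beta, c2$beta)
  expect_equal(c1$gamma, c2$gamma)

  # linear-in-p beta is absorbed entirely: beta becomes all-zero
  plin <- apc_parameters(-8, rnorm(10), 0.3 - 0.05 * (1:6), rnorm(15))
  cl <- apply_constraints(plin, spec)
  expect_equal(cl$beta, rep(0, 6), tolerance = 1e-12)
  expect_equal(apc_log_rate(cl, g), apc_log_rate(plin, g), tolerance = 1e-12)

  set.seed(21)
  for (rep in 1:50) {
    pars <- random_params(g)
    con <- apply_constraints(pars, spec)
    expect_equal(con$beta[2], 0, tolerance = 1e-12)
    expect_equal(con$beta[5], 0, tolerance = 1e-12)
    expect_equal(con$gamma[8], 0, tolerance = 1e-12)
    expect_equal(mean(con$alpha), 0, tolerance = 1e-12)
    eta0 <- apc_log_rate(pars, g)
    eta1 <- apc_log_rate(con, g)
    expect_lt(max(abs(eta1 - eta0) / pmax(abs(eta0), 1e-8)), 1e-10)
  }

  # submodels: included effects centred, fitted rates unchanged
  spec_ap <- apc_model_spec(g, include_cohort = FALSE)
  pars <- random_params(g)
  pars$gamma <- rep(0, 15)
  con <- apply_constraints(pars, spec_ap)
  expect_equal(mean(con$alpha), 0, tolerance = 1e-12)
  expect_equal(mean(con$beta), 0, tolerance = 1e-12)
  expect_equal(apc_log_rate(con, g, spec = spec_ap),
               apc_log_rate(pars, g, spec = spec_ap), tolerance = 1e-12)

  expect_error(apc_model_spec(lexis_grid(n_age = 5, n_period = 2)),
               "degenerate")
})

test_that("split-chain Rhat matches an explicit variance-decomposition oracle", {
  # identical chains: 1 up to the split-halving correction sqrt((n-1)/n)
  set.seed(2)
  x <- rnorm(200)
  expect_equal(rhat(cbind(x, x, x)), 1, tolerance = 0.01)
  expect_gte(rhat(cbind(x, x, x)), sqrt(99 / 100))

  # constant chains at distinct values: flagged Inf, not NaN
  expect_identical(rhat(cbind(rep(1, 50), rep(2, 50))), Inf)
  expect_identical(rhat(cbind(rep(1, 50), rep(1, 50))), 1.0)

  # simulated AR(1) chains vs the textbook formula
  for (rep in 1:5) {
    m <- matrix(NA_real_, 500, 4)
    for (k in 1:4) {
      z <- numeric(500); z[1] <- rnorm(1, mean = k)
      for (t in 2:500) z[t] <- 0.6 * z[t - 1] + rnorm(1, sd = 0.5)
      m[, k] <- z
    }
    expect_equal(rhat(m), rhat_oracle(m), tolerance = 1e-12)
  }
  expect_error(rhat(matrix(1, 10, 1)), "2 chains")
})

test_that("identical seeds give bit-identical retained chains", {
  fx <- cached_fit()
  cfg <- quick_mcmc(seed = 55L, n_keep_total = 400L, burn_in = 200L,
                    rhat_threshold = 10)  # no convergence looping: fixed length
  p1 <- suppressWarnings(sample_posterior(fx$counts, fx$spec, cfg))
  p2 <- suppressWarnings(sample_posterior(fx$counts, fx$spec, cfg))
  expect_identical(p1$draws, p2$draws)
  cfg2 <- cfg; cfg2$seed <- 56L
  p3 <- suppressWarnings(sample_posterior(fx$counts, fx$spec, cfg2))
  expect_false(identical(p1$draws, p3$draws))
})

test_that("every retained draw satisfies the reference constraints", {
  fx <- cached_fit()
  d <- as_draws_matrix(fx$posterior)
  expect_true(all(abs(d[, "beta[2]"]) < 1e-12))
  expect_true(all(abs(d[, "beta[5]"]) < 1e-12))
  expect_true(all(abs(d[, "gamma[8]"]) < 1e-12))
  alpha_cols <- grep("^alpha", colnames(d))
  expect_true(all(abs(rowMeans(d[, alpha_cols])) < 1e-10))
})

test_that("flat-signal data yield RR intervals covering 1 everywhere", {
  g <- lexis_grid()
  py <- matrix(2e5, 10, 6)
  set.seed(31)
  d <- matrix(rpois(60, 2e5 * 3e-4), 10, 6)  # same rate in every cell
  cnt <- stratum_counts(g, "male", "low", d, py)
  post <- suppressWarnings(sample_posterior(cnt, apc_model_spec(g),
                                            quick_mcmc(3L)))
  rr <- relative_risks(post)
  expect_true(all(rr$cohort$lo95 <= 1 & rr$cohort$hi95 >= 1))
  expect_true(all(rr$period$lo95 <= 1 & rr$period$hi95 >= 1))
})

test_that("relative risks exponentiate and summarize the effect draws", {
  g <- lexis_grid()
  pars <- apply_constraints(random_params(g), apc_model_spec(g))
  post <- degenerate_posterior(pars, g)
  rr <- relative_risks(post)
  # reference categories: RR identically 1 with zero-width intervals
  expect_equal(rr$period$rr[2], 1)
  expect_equal(rr$period$hi95[2] - rr$period$lo95[2], 0)
  expect_equal(rr$cohort$rr[8], 1)
  expect_equal(rr$cohort$rr, exp(pars$gamma))
  expect_equal(rr$cohort$center_year,
               cohort_center_years(1:15, g))

  # ln 2 effect in all draws: RR exactly 2
  pars2 <- pars; pars2$gamma <- rep(log(2), 15)
  rr2 <- relative_risks(degenerate_posterior(pars2, g))
  expect_equal(rr2$cohort$rr, rep(2, 15))

  # random draws: exp-then-summarize oracle on a hand-built posterior
  fx <- cached_fit()
  d <- as_draws_matrix(fx$posterior)
  col <- "gamma[3]"
  oracle_mean <- mean(exp(d[, col]))
  oracle_q <- sort_quantile(exp(d[, col]), c(0.025, 0.975))
  rr3 <- relative_risks(fx$posterior)
  expect_equal(rr3$cohort$rr[3], oracle_mean, tolerance = 1e-12)
  expect_equal(rr3$cohort$lo95[3], oracle_q[1], tolerance = 1e-10)
})

test_that("DIC reduces to Dbar for a degenerate posterior and penalizes complexity", {
  fx <- cached_fit()
  pars <- posterior_mean_params(fx$posterior)
  post0 <- degenerate_posterior(pars, fx$counts$grid)
  dd <- dic(post0, fx$counts)
  expect_equal(dd$pd, 0, tolerance = 1e-6)
  expect_equal(dd$dic, dd$dbar, tolerance = 1e-6)
  expect_equal(dd$dic, dd$dbar + dd$pd)  # exact identity

  # on the real fit pD is positive and below the free-parameter count (28)
  dd1 <- dic(fx$posterior, fx$counts)
  expect_gt(dd1$pd, 0)
  expect_lt(dd1$pd, 28)
})

test_that("posterior dominates the prior on large-count data", {
  g <- lexis_grid()
  truth <- default_scenario("male", "low")
  truth$person_years <- matrix(1e7, 10, 6)
  cnt <- simulate_grid_counts(truth, seed = 77L)
  cfg <- quick_mcmc(seed = 5L, n_keep_total = 2000L, burn_in = 1000L,
                    rhat_threshold = 1.2)
  m1 <- suppressWarnings(sample_posterior(cnt, apc_model_spec(g), cfg))
  m2 <- suppressWarnings(sample_posterior(cnt,
          apc_model_spec(g, hyper_rate = 0.002), cfg))
  eta1 <- as.numeric(apc_log_rate(posterior_mean_params(m1), g))
  eta2 <- as.numeric(apc_log_rate(posterior_mean_params(m2), g))
  expect_lt(max(abs(eta1 - eta2) / abs(eta1)), 0.001)
})

test_that("non-convergence within the burn-in budget is flagged, never silent", {
  fx <- cached_fit()
  cfg <- mcmc_config(n_chains = 2L, n_keep_total = 100L, burn_in = 5L,
                     max_burn_in = 10L, rhat_threshold = 1.0001, seed = 2L)
  expect_warning(post <- sample_posterior(fx$counts, fx$spec, cfg),
                 "did not converge")
  expect_false(post$converged)
  expect_true(max(post$rhat, na.rm = TRUE) > 1.0001)
})

test_that("submodel comparison fits all seven combinations", {
  fx <- cached_fit()
  cfg <- mcmc_config(n_chains = 2L, n_keep_total = 600L, burn_in = 300L,
                     max_burn_in = 600L, rhat_threshold = 5, seed = 4L)
  cmp <- suppressWarnings(compare_models(fx$counts, fx$counts$grid, cfg))
  expect_identical(nrow(cmp), 7L)
  expect_setequal(cmp$model, c("age", "period", "cohort", "age-period",
                               "age-cohort", "period-cohort",
                               "age-period-cohort"))
  expect_true(all(is.finite(cmp$dic)))
  expect_identical(cmp$model[1], cmp$model[which.min(cmp$dic)])
})
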
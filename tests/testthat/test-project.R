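test_that("zero innovation variance gives exact linear extrapolation", {
  g <- lexis_grid()
  pars <- apply_constraints(random_params(g), apc_model_spec(g))
  pars$beta <- c(0.3, 0, -0.1, -0.1, 0, 0.1)
  pars$beta[5:6] <- c(0.1, 0.2)  # linear tail, slope 0.1
  pars$sigma2 <- c(age = 0, period = 0, cohort = 0)
  post <- degenerate_posterior(pars, g)
  ext <- extend_effects(post, n_ahead = 3, seed = 1)
  expect_equal(unname(ext$beta[1, 7:9]), c(0.3, 0.4, 0.5), tolerance = 1e-12)

  # constant tail stays constant
  pars2 <- pars; pars2$beta[5:6] <- c(0.25, 0.25)
  ext2 <- extend_effects(degenerate_posterior(pars2, g), n_ahead = 3, seed = 1)
  expect_equal(unname(ext2$beta[1, 7:9]), rep(0.25, 3), tolerance = 1e-12)

  # observed-window columns equal the fitted draws exactly
  expect_equal(unname(ext$beta[, 1:6]),
               unname(as_draws_matrix(post)[, sprintf("beta[%d]", 1:6)]))
  expect_equal(unname(ext$gamma[, 1:15]),
               unname(as_draws_matrix(post)[, sprintf("gamma[%d]", 1:15)]))
  expect_error(extend_effects(post, n_ahead = 0), "n_ahead")
})

test_that("predictive extension is centred on the linear extrapolation", {
  g <- lexis_grid()
  pars <- apply_constraints(random_params(g), apc_model_spec(g))
  pars$sigma2 <- c(age = 0, period = 0.04, cohort = 0.04)
  post <- degenerate_posterior(pars, g, n_draws = 50000L, n_chains = 2L)
  ext <- extend_effects(post, n_ahead = 1, seed = 3)
  expected <- 2 * pars$beta[6] - pars$beta[5]
  se <- sqrt(0.04 / 1e5)
  expect_lt(abs(mean(ext$beta[, 7]) - expected), 3 * se)
  # and the spread matches the innovation sd
  expect_equal(sd(ext$beta[, 7]), 0.2, tolerance = 0.02)
})

test_that("projected rates follow the extended diagonal and its guard rails", {
  g <- lexis_grid()
  pars <- apc_parameters(0, rep(0, 10), rep(0, 6), rep(0, 15),
                         sigma2 = c(age = 0, period = 0, cohort = 0))
  post <- degenerate_posterior(pars, g)
  ext <- extend_effects(post, n_ahead = 3, seed = 1)
  rates <- project_rates(post, ext)
  expect_equal(dim(rates), c(100L, 10L, 3L))
  expect_equal(as.numeric(rates), rep(1e5, length(rates)))  # lambda = 1

  # 10 x (6+3) extended grid needs cohorts up to exactly 18
  expect_identical(cohort_index(1, 9, g), 18L)
  expect_identical(ncol(ext$gamma), 18L)
  # cohort labels of the three projected cohorts
  expect_identical(cohort_label(16:18, g)$center_year, c(1976L, 1981L, 1986L))

  # missing extended cohort effects are caught (off-by-one guard)
  ext_bad <- ext
  ext_bad$gamma <- ext_bad$gamma[, 1:17]
  expect_error(project_rates(post, ext_bad), "cohort 18")

  # per-draw loop oracle on a non-trivial posterior
  fx <- cached_fit()
  ext2 <- extend_effects(fx$posterior, n_ahead = 3, seed = 9)
  r2 <- project_rates(fx$posterior, ext2)
  d <- as_draws_matrix(fx$posterior)
  set.seed(1)
  for (i in sample(nrow(d), 5)) for (a in c(1, 5, 10)) for (j in 1:3) {
    ci <- cohort_index(a, 6 + j, g)
    expect_equal(r2[i, a, j],
                 unname(1e5 * exp(d[i, "mu"] + d[i, sprintf("alpha[%d]", a)] +
                                    ext2$beta[i, 6 + j] + ext2$gamma[i, ci])),
                 tolerance = 1e-12)
  }
})

test_that("ASR series concatenates fitted and projected periods with widening intervals", {
  fx <- cached_fit()
  proj <- project_mortality(fx$posterior, n_ahead = 3, seed = 11)
  s <- proj$asr_series
  expect_identical(nrow(s), 9L)
  expect_identical(s$observed_or_projected, rep(c("observed", "projected"),
                                                c(6, 3)))
  expect_identical(s$period[7:9], c("2006-2010", "2011-2015", "2016-2020"))
  expect_equal(s$center_year[7:9], c(2008, 2013, 2018))
  expect_true(all(s$asr_lo <= s$asr & s$asr <= s$asr_hi))
  expect_true(all(s$asr_lo >= 0))
  # predictive uncertainty accumulates across the projected periods
  w <- s$asr_hi - s$asr_lo
  expect_true(w[7] < w[8] && w[8] < w[9])

  # compose-then-summarize oracle for a projected period
  std <- restrict_weights(who_standard(), fx$counts$grid)
  asr_draws <- proj$projected_rates[, , 2] %*% std$weight
  expect_equal(s$asr[8], mean(asr_draws), tolerance = 1e-12)
  expect_equal(s$asr_lo[8], sort_quantile(asr_draws, 0.025), tolerance = 1e-10)

  # degenerate posterior: zero-width intervals everywhere
  g <- lexis_grid()
  pars <- apply_constraints(random_params(g, 0.2), apc_model_spec(g))
  pars$sigma2 <- c(age = 0, period = 0, cohort = 0)
  p0 <- project_mortality(degenerate_posterior(pars, g), seed = 2)
  expect_equal(p0$asr_series$asr_hi, p0$asr_series$asr_lo, tolerance = 1e-9)
})

test_that("projection of the synthetic truth covers its future ASRs", {
  # deterministic continuation of the generating truth inside the 95% band
  truth <- default_scenario("male", "low")
  g <- truth$grid
  hits <- 0L
  n_rep <- 5L
  for (r in seq_len(n_rep)) {
    cnt <- simulate_grid_counts(truth, seed = 500L + r)
    post <- suppressWarnings(sample_posterior(cnt, apc_model_spec(g),
                                              quick_mcmc(r)))
    s <- project_mortality(post, seed = r)$asr_series
    tf <- scenario_asr(truth, 7:9)
    hits <- hits + all(tf >= s$asr_lo[7:9] & tf <= s$asr_hi[7:9])
  }
  expect_gte(hits, n_rep - 1L)
})
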
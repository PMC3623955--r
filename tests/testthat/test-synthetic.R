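test_that("scenario truths encode the documented qualitative structure", {
  g <- lexis_grid()
  for (s in c("female", "male")) for (i in c("low", "high")) {
    tr <- default_scenario(s, i)
    # age effects strictly increasing with the slope jump at 50-54 (group 5)
    expect_true(all(diff(tr$alpha) > 0))
    d2a <- diff(tr$alpha, differences = 2)
    expect_identical(which.max(d2a) + 1L, 5L)
    # constraints pre-applied
    expect_equal(tr$beta[2], 0, tolerance = 1e-12)
    expect_equal(tr$beta[5], 0, tolerance = 1e-12)
    expect_equal(tr$gamma[8], 0, tolerance = 1e-12)
    # first-period ASR hits the anchor
    expect_equal(scenario_asr(tr, 1), tr$anchors[1], tolerance = 1e-6)
    expect_equal(scenario_asr(tr, 9), tr$anchors[2], tolerance = 1e-6)
    expect_true(all(tr$person_years > 0))
  }

  # the 1945-50 upturn is male-only: female second difference at the cohort
  # centred on 1946 (index 10) is non-positive
  d2_at_1946 <- function(tr) diff(tr$gamma, differences = 2)[9]
  expect_lte(d2_at_1946(default_scenario("female", "low")), 1e-10)
  expect_lte(d2_at_1946(default_scenario("female", "high")), 1e-10)
  expect_gt(d2_at_1946(default_scenario("male", "low")), 0.2)
  expect_gt(d2_at_1946(default_scenario("male", "high")), 0.1)
  # more obvious for low-income men
  expect_gt(d2_at_1946(default_scenario("male", "low")),
            d2_at_1946(default_scenario("male", "high")))

  # higher male than female rates throughout
  expect_gt(scenario_asr(default_scenario("male", "low"), 3),
            scenario_asr(default_scenario("female", "low"), 3))
})

test_that("high/low income ASRs cross over between first and last periods", {
  for (s in c("female", "male")) {
    lo <- default_scenario(s, "low")
    hi <- default_scenario(s, "high")
    expect_gt(scenario_asr(hi, 1), scenario_asr(lo, 1))  # high starts higher
    expect_lt(scenario_asr(hi, 6), scenario_asr(lo, 6))  # reversed when observed ends
    expect_lt(scenario_asr(hi, 9), scenario_asr(lo, 9))  # and stays reversed
  }
})

test_that("grid count simulation is Poisson with the truth's means", {
  truth <- default_scenario("male", "low")
  c1 <- simulate_grid_counts(truth, seed = 4)
  c2 <- simulate_grid_counts(truth, seed = 4)
  expect_identical(c1$deaths, c2$deaths)   # same seed, same matrices
  c3 <- simulate_grid_counts(truth, seed = 5)
  expect_false(identical(c1$deaths, c3$deaths))

  # CLT check on replicate draws: cell means within 3 standard errors of
  # N * lambda (checked on a 3x3 subgrid to keep the loop small)
  pars <- apc_parameters(truth$mu, truth$alpha, truth$beta, truth$gamma)
  lam <- truth$person_years * exp(apc_log_rate(pars, truth$grid))
  n_rep <- 2000L
  sums <- matrix(0, 3, 3)
  for (r in seq_len(n_rep))
    sums <- sums + simulate_grid_counts(truth, seed = 10000L + r)$deaths[1:3, 1:3]
  mean_hat <- sums / n_rep
  se <- sqrt(lam[1:3, 1:3] / n_rep)
  expect_true(all(abs(mean_hat - lam[1:3, 1:3]) < 3.5 * se))
})

test_that("record expansion round-trips through classification and aggregation", {
  truth <- default_scenario("female", "high")
  sim <- simulate_records(truth, seed = 8)
  expect_true(all(is_ihd(sim$records$icd_code, sim$records$icd_revision)))

  assignment <- classify_tpus(sim$tpu_table)
  # both strata populated in every census year
  for (cy in unique(assignment$census_year)) {
    grp <- assignment$income_group[assignment$census_year == cy]
    expect_true(all(c("low", "high") %in% grp))
  }

  agg <- aggregate_deaths(sim$records, truth$grid, assignment)
  expect_identical(agg$deaths$female.high, sim$counts$deaths)
  expect_identical(agg$retained, nrow(sim$records))
  # no leakage into other strata
  expect_identical(sum(agg$deaths$female.low), 0L)
  expect_identical(sum(agg$deaths$male.low) + sum(agg$deaths$male.high), 0L)

  # population denominators aggregate back to the person-years schedule
  py <- aggregate_population(sim$population, truth$grid, assignment)
  expect_equal(py$female.high, sim$counts$person_years, tolerance = 1e-8)
})

test_that("scenario truth serializes losslessly", {
  truth <- default_scenario("male", "high")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth(truth, path)
  back <- read_truth(path)
  expect_equal(back$mu, truth$mu, tolerance = 1e-12)
  expect_equal(back$alpha, truth$alpha, tolerance = 1e-12)
  expect_equal(back$beta, truth$beta, tolerance = 1e-12)
  expect_equal(back$gamma, truth$gamma, tolerance = 1e-12)
  expect_equal(back$person_years, truth$person_years, tolerance = 1e-10)
  expect_identical(back$sex, "male")
  expect_identical(back$grid$n_cohorts, truth$grid$n_cohorts)
})
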
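test_that("cohort index follows the Lexis anti-diagonals", {
  g <- lexis_grid()
  expect_identical(cohort_index(1, 1, g), 10L)
  expect_identical(cohort_index(10, 1, g), 1L)
  expect_identical(cohort_index(1, 6, g), 15L)
  expect_identical(cohort_index(1, 9, g), 18L)  # projection cell
  expect_error(cohort_index(0, 1, g), "age_idx")
  expect_error(cohort_index(11, 1, g), "age_idx")
  expect_error(cohort_index(1, 0, g), "period_idx")

  # enumerating all 60 cells yields exactly 15 distinct cohorts; the 10x9
  # extended grid yields 18, matching brute-force diagonal enumeration
  for (P in c(6L, 9L)) {
    cells <- expand.grid(a = 1:10, p = seq_len(P))
    idx <- cohort_index(cells$a, cells$p, g)
    expect_true(all(idx >= 1 & idx <= 10 + P - 1))
    expect_identical(sort(unique(idx)), seq_len(10L + P - 1L))
    # brute force: group cells by p - a; diagonals in increasing order
    diag_id <- cells$p - cells$a
    expect_identical(idx, diag_id - min(diag_id) + 1L)
  }

  # diagonal structure: +1 per period step, -1 per (younger) age step
  for (a in 2:10) for (p in 2:6) {
    expect_identical(cohort_index(a, p, g) - cohort_index(a, p - 1, g), 1L)
    expect_identical(cohort_index(a, p, g) - cohort_index(a - 1, p, g), -1L)
  }
})

test_that("cohort labels are 10-year spans centred at 5-year intervals from 1901", {
  g <- lexis_grid()
  lab <- cohort_label(1:18, g)
  expect_identical(lab$center_year[c(1, 8, 10, 15)],
                   c(1901L, 1936L, 1946L, 1971L))
  expect_true(all(diff(lab$center_year) == 5L))
  expect_true(all(lab$span_end - lab$span_start == 10L))
  expect_identical(lab$center_year, (lab$span_start + lab$span_end) %/% 2L)
})

test_that("grid constructor validates and derives cohort count", {
  g <- lexis_grid()
  expect_identical(g$n_cohorts, 15L)
  expect_identical(g$age_lower_edges, seq(30L, 75L, by = 5L))
  expect_identical(g$period_start_years, seq(1976L, 2001L, by = 5L))
  expect_equal(period_centers(g), seq(1978, 2003, by = 5))
  expect_error(lexis_grid(period_width = 10), "period_width")
  g2 <- lexis_grid(n_age = 4L, n_period = 3L)
  expect_identical(g2$n_cohorts, 6L)
})

test_that("IHD classification covers ICD-8/9 rubrics 410-414 and ICD-10 I20-I25", {
  expect_true(is_ihd("4149", 9))
  expect_true(is_ihd("I21.9", 10))
  expect_false(is_ihd("I26", 10))
  expect_true(is_ihd("410", 8))
  expect_true(is_ihd("414.9", 9))
  expect_false(is_ihd("409", 9))
  expect_false(is_ihd("415", 9))
  expect_false(is_ihd("I19", 10))
  expect_false(is_ihd("E410", 10))   # wrong letter
  # enumerate every I20-I25 subcode
  subcodes <- as.vector(outer(sprintf("I2%d", 0:5), c("", paste0(".", 0:9)),
                              paste0))
  expect_true(all(is_ihd(subcodes, 10)))
  # unparseable codes are flagged NA, never silently FALSE
  expect_true(is.na(is_ihd("??", 9)))
  expect_true(is.na(is_ihd("4x0", 10)))
  expect_true(is.na(is_ihd("410", 7)))   # unknown revision
  # vectorized with recycling
  expect_identical(is_ihd(c("410", "I24", "999"), c(9, 10, 9)),
                   c(TRUE, TRUE, FALSE))
})

test_that("filter_ihd drops non-IHD and reports unparseable codes", {
  rec <- data.frame(icd_code = c("410", "I26", "bad", "I21.4"),
                    icd_revision = c(9, 10, 10, 10))
  out <- filter_ihd(rec)
  expect_identical(nrow(out), 2L)
  expect_identical(attr(out, "invalid"), 1L)
})

test_that("record aggregation maps each record to exactly one cell", {
  g <- lexis_grid()
  rec <- data.frame(age = 77, sex = "male", year = 1990, tpu_id = "x",
                    income_group = "low")
  agg <- aggregate_deaths(rec, g)
  expect_identical(agg$retained, 1L)
  expect_identical(agg$deaths$male.low[10, 3], 1L)  # 75+, 1986-1990
  expect_identical(sum(unlist(agg$deaths)), 1L)

  empty <- aggregate_deaths(rec[0, ], g)
  expect_true(all(unlist(empty$deaths) == 0L))
  expect_identical(empty$retained, 0L)
})

test_that("aggregation equals a dictionary-count oracle and conserves records", {
  g <- lexis_grid()
  set.seed(42)
  n <- 1000L
  rec <- data.frame(age = sample(20:95, n, replace = TRUE),
                    sex = sample(c("female", "male"), n, replace = TRUE),
                    year = sample(1970:2010, n, replace = TRUE),
                    tpu_id = "t",
                    income_group = sample(c("low", "high"), n, replace = TRUE))
  agg <- aggregate_deaths(rec, g)
  expect_identical(agg$retained + sum(agg$dropped$n), n)

  # independent tally: dictionary counting per stratum/cell
  in_age <- rec$age >= 30
  in_year <- rec$year >= 1976 & rec$year <= 2005
  kept <- rec[in_age & in_year, ]
  a_idx <- pmin(floor((kept$age - 30) / 5) + 1, 10)
  p_idx <- floor((kept$year - 1976) / 5) + 1
  for (s in c("female", "male")) for (i in c("low", "high")) {
    sel <- kept$sex == s & kept$income_group == i
    key <- paste(a_idx[sel], p_idx[sel])
    tallied <- table(key)
    m <- agg$deaths[[paste(s, i, sep = ".")]]
    for (nm in names(tallied)) {
      ap <- as.integer(strsplit(nm, " ")[[1]])
      expect_identical(m[ap[1], ap[2]], as.integer(tallied[[nm]]))
    }
    expect_identical(sum(m), sum(sel))
  }
  expect_identical(agg$dropped$n[agg$dropped$reason == "age_below_grid"],
                   sum(!in_age))
  expect_identical(agg$dropped$n[agg$dropped$reason == "year_outside_periods"],
                   sum(in_age & !in_year))
})

test_that("crude rates are deaths per 100,000 person-years, cell-wise", {
  g <- lexis_grid(n_age = 2, n_period = 2)
  cnt <- stratum_counts(g, "male", "low", matrix(c(5, 0, 2, 1), 2, 2),
                        matrix(1e5, 2, 2))
  r <- crude_rates(cnt)
  expect_equal(r[1, 1], 5)
  expect_equal(r[2, 1], 0)

  set.seed(1)
  d <- matrix(rpois(4, 20), 2, 2)
  py <- matrix(runif(4, 1e4, 1e6), 2, 2)
  cnt <- stratum_counts(g, "female", "high", d, py)
  r <- crude_rates(cnt)
  for (a in 1:2) for (p in 1:2)    # scalar loop oracle
    expect_equal(r[a, p], 1e5 * d[a, p] / py[a, p])

  expect_error(stratum_counts(g, "male", "low", matrix(0, 2, 2),
                              matrix(c(1, 0, 1, 1), 2, 2)), "positive")
  expect_error(stratum_counts(g, "male", "low", matrix(-1, 2, 2),
                              matrix(1, 2, 2)), "non-negative")
})
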
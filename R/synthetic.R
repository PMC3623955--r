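#' Synthetic-scenario ground truth for one sex x income stratum
#'
#' The generator emulates the qualitative structure of stratified
#' ischaemic-heart-disease mortality in a rapidly transitioning population:
#'
#' * age effects increase with a positive jump in slope at the 50-54 group
#'   (the acceleration near age 50);
#' * period effects are pinned to zero at the reference periods, with a
#'   low-income-only dip in the early 1990s followed by a late-1990s upturn,
#'   and only minor period structure in the high-income strata;
#' * cohort effects decline overall (the main driver of falling rates), with
#'   a marked male upturn at the cohort centred on 1946 (more pronounced for
#'   low-income men), a female downturn around the early-1920s cohorts, and a
#'   slight upturn near 1941 for high-income women only.
#'
#' The intercept is calibrated so the first-period age-standardized rate
#' (30+, WHO standard) hits the stratum's anchor, and the base cohort slope
#' is solved so the deterministic (zero-innovation) extension three periods
#' ahead hits the end anchor. Low-income anchors are 33.3 -> 19.7 per
#' 100,000 (women) and 55.5 -> 34.2 (men); high-income anchors (38 -> 13 and
#' 76 -> 23) encode initially higher rates that fall faster, reversing the
#' social gradient before the end of the observed window.
#'
#' @param sex `"female"` or `"male"`.
#' @param income_group `"low"` or `"high"`.
#' @param grid A [lexis_grid()] (default 10 x 6).
#' @param anchors Optional numeric pair `c(first, last)` overriding the
#'   stratum's ASR anchors (per 100,000) at the first observed and last
#'   projected period.
#' @return An object of class `scenario_truth`: constrained true parameters
#'   (`mu`, `alpha`, `beta`, `gamma`, `sigma2`) plus the person-years
#'   schedule `person_years`.
#' @export
default_scenario <- function(sex = c("female", "male"),
                             income_group = c("low", "high"),
                             grid = lexis_grid(), anchors = NULL) {
  sex <- match.arg(sex)
  income_group <- match.arg(income_group)
  A <- grid$n_age; P <- grid$n_period; C <- grid$n_cohorts

  # age: slope 0.35/group up to 50-54 (group 5), 0.55 after
  a_step <- c(rep(0.35, 4), rep(0.55, A - 5))
  alpha <- c(0, cumsum(a_step))

  # period wiggles around zero, already zero at the reference periods (2, 5)
  beta <- if (income_group == "low")
    c(0.02, 0, -0.02, -0.12, 0, 0.04)[seq_len(P)]
  else
    c(0.01, 0, -0.01, -0.03, 0, 0.01)[seq_len(P)]

  # cohort step deviations from the calibrated base slope
  dev <- rep(0, C)
  if (sex == "male") {
    # decline steepens just before the marked 1946-cohort upturn, making the
    # upturn one-sided (its second difference concentrates at one cohort)
    dev[2:9] <- -0.02
    if (income_group == "low") {
      dev[10] <- -0.08; dev[11] <- 0.42; dev[12] <- 0.22
    } else {
      dev[10] <- -0.06; dev[11] <- 0.30; dev[12] <- 0.16
    }
    dev[13:C] <- -0.06
  } else {
    dev[2:5] <- 0.08
    dev[6:C] <- -0.032
    if (income_group == "high") dev[10] <- dev[10] + 0.02
  }

  anchor_tab <- list(female.low = c(33.3, 19.7), male.low = c(55.5, 34.2),
                     female.high = c(38, 13), male.high = c(76, 23))
  if (is.null(anchors)) anchors <- anchor_tab[[paste(sex, income_group, sep = ".")]]

  # person-years: mid-year population declining with age and growing over
  # time, at magnitudes comparable to a Hong-Kong-scale income stratum
  # (~0.3-0.9 million person-years per cell)
  pop <- outer(seq_len(A), seq_len(P),
               function(a, p) 150000 * exp(-0.10 * (a - 1)) * 1.04^(p - 1))
  py <- grid$period_width * pop

  std <- restrict_weights(who_standard(), grid)
  spec <- apc_model_spec(grid)

  make_truth <- function(slope, mu) {
    gamma <- c(0, cumsum(slope + dev[-1]))
    pars <- apc_parameters(mu, alpha, beta, gamma,
                           sigma2 = c(age = 1e-4, period = 1e-4, cohort = 4e-4),
                           grid = grid)
    apply_constraints(pars, spec)
  }
  asr_at <- function(pars, period_idx) {
    .truth_asr(pars, grid, std, period_idx)
  }
  # solve the base cohort slope from the anchor ratio (mu cancels), then mu
  target_ratio <- anchors[2] / anchors[1]
  f <- function(s) {
    p <- make_truth(s, 0)
    asr_at(p, P + 3L) / asr_at(p, 1L) - target_ratio
  }
  slope <- stats::uniroot(f, c(-0.6, 0.3), tol = 1e-10)$root
  p0 <- make_truth(slope, 0)
  mu <- log(anchors[1] / asr_at(p0, 1L))
  pars <- make_truth(slope, mu)

  structure(list(grid = grid, sex = sex, income_group = income_group,
                 mu = pars$mu, alpha = pars$alpha, beta = pars$beta,
                 gamma = pars$gamma, sigma2 = pars$sigma2,
                 person_years = py, anchors = anchors,
                 base_cohort_slope = slope),
            class = "scenario_truth")
}

# ASR of a truth parameter set at an (optionally future) period, using the
# deterministic linear extrapolation of the beta and gamma tails
.truth_asr <- function(pars, grid, std, period_idx) {
  P <- grid$n_period; C <- grid$n_cohorts; A <- grid$n_age
  n_extra <- max(0L, period_idx - P)
  beta <- pars$beta; gamma <- pars$gamma
  for (j in seq_len(n_extra)) {
    beta <- c(beta, 2 * beta[length(beta)] - beta[length(beta) - 1])
  }
  need_c <- (A - 1L) + period_idx
  while (length(gamma) < need_c)
    gamma <- c(gamma, 2 * gamma[length(gamma)] - gamma[length(gamma) - 1])
  rates <- vapply(seq_len(A), function(a) {
    ci <- (A - a) + period_idx
    1e5 * exp(pars$mu + pars$alpha[a] + beta[period_idx] + gamma[ci])
  }, numeric(1))
  direct_asr(rates, std)
}

#' Age-standardized rate implied by a scenario truth
#'
#' Periods beyond the observed window use the deterministic (zero-innovation)
#' linear extension of the period and cohort effect tails.
#'
#' @param truth A [default_scenario()] result.
#' @param period_idx Period index, possibly beyond `n_period`.
#' @return ASR per 100,000 over the grid's age range.
#' @export
scenario_asr <- function(truth, period_idx) {
  std <- restrict_weights(who_standard(), truth$grid)
  pars <- apc_parameters(truth$mu, truth$alpha, truth$beta, truth$gamma)
  vapply(period_idx, function(p) .truth_asr(pars, truth$grid, std, p),
         numeric(1))
}

#' Simulate grid-level death counts from a scenario truth
#'
#' `D[a,p] ~ Poisson(N[a,p] * exp(eta_truth(a, p)))`, independently per cell.
#'
#' @param truth A [default_scenario()] result.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return A [stratum_counts()].
#' @export
simulate_grid_counts <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "scenario_truth"))
  grid <- truth$grid
  pars <- apc_parameters(truth$mu, truth$alpha, truth$beta, truth$gamma)
  lam <- truth$person_years * exp(apc_log_rate(pars, grid))
  if (any(!is.finite(lam)) || any(lam > 2^31))
    stop("expected counts overflow: rescale the population schedule")
  set.seed(seed)
  d <- matrix(stats::rpois(length(lam), lam), grid$n_age, grid$n_period)
  stratum_counts(grid, truth$sex, truth$income_group, d, truth$person_years)
}

#' Synthetic TPU median-income table
#'
#' Builds a census-year by TPU table whose incomes straddle each year's
#' median, so both income strata are always populated. An odd TPU count
#' keeps the intended halves stable under the lower-middle median rule.
#'
#' @param n_tpu Number of TPUs (default 41).
#' @param census_years Census years (default 1976, 1981, ..., 2006).
#' @param seed Integer seed.
#' @return data.frame `tpu_id`, `census_year`, `median_income_per_capita`.
#' @export
make_tpu_income_table <- function(n_tpu = 41L,
                                  census_years = seq(1976L, 2006L, by = 5L),
                                  seed = 1L) {
  set.seed(seed)
  n_low <- n_tpu %/% 2L
  tpu <- sprintf("TPU%03d", seq_len(n_tpu))
  rows <- lapply(seq_along(census_years), function(i) {
    growth <- 1.35^(i - 1)  # nominal income growth between censuses
    inc <- c(stats::runif(n_low, 4000, 9000),
             stats::runif(n_tpu - n_low, 11000, 30000)) * growth
    data.frame(tpu_id = tpu, census_year = census_years[i],
               median_income_per_capita = inc)
  })
  do.call(rbind, rows)
}

.icd_code_for_year <- function(year) {
  # revision eras: ICD-8 before 1980, ICD-9 1980-2000, ICD-10 from 2001
  if (year < 1980) {
    list(revision = 8L, codes = c("410", "411", "412", "413", "414"))
  } else if (year <= 2000) {
    list(revision = 9L, codes = c("410", "4109", "411", "412", "4129",
                                  "413", "414", "4140", "4149"))
  } else {
    list(revision = 10L, codes = c("I20", "I20.9", "I21", "I21.4", "I21.9",
                                   "I22", "I23", "I24", "I25", "I25.1"))
  }
}

#' Expand a scenario into individual death records plus denominators
#'
#' Simulates grid counts, then expands every cell into individual death
#' records with ages and years uniform within the cell, era-appropriate IHD
#' ICD codes, and TPU ids drawn from the pool whose classified income group
#' (at the census nearest the death year) matches the stratum — so
#' aggregating the records through [classify_tpus()]/[stratum_of()] exactly
#' reproduces the grid counts they were expanded from. Annual population
#' denominators are distributed over three TPUs of the matching pool.
#'
#' @param truth A [default_scenario()] result.
#' @param tpu_table Income table from [make_tpu_income_table()] (one table
#'   can be shared across strata).
#' @param seed Integer seed.
#' @return List with `records` (death records data.frame), `population`
#'   (annual denominators data.frame), `tpu_table`, `counts` (the underlying
#'   [stratum_counts()]).
#' @export
simulate_records <- function(truth, tpu_table = make_tpu_income_table(seed = seed),
                             seed = 1L) {
  counts <- simulate_grid_counts(truth, seed)
  grid <- truth$grid
  assignment <- classify_tpus(tpu_table)
  set.seed(seed + 1L)

  pool_for <- function(year) {
    cy <- nearest_census(year, assignment$census_year)
    sub <- assignment[assignment$census_year == cy &
                        assignment$income_group == truth$income_group, ]
    sub$tpu_id
  }

  recs <- list()
  for (p in seq_len(grid$n_period)) {
    years <- grid$period_start_years[p] + 0:(grid$period_width - 1L)
    for (a in seq_len(grid$n_age)) {
      d <- counts$deaths[a, p]
      if (d == 0) next
      yr <- sample(years, d, replace = TRUE)
      age_lo <- grid$age_lower_edges[a]
      age_hi <- if (a == grid$n_age && grid$open_ended_top)
        age_lo + 2L * grid$age_width - 1L else age_lo + grid$age_width - 1L
      age <- sample(age_lo:age_hi, d, replace = TRUE)
      icd <- lapply(yr, function(y) {
        e <- .icd_code_for_year(y)
        list(revision = e$revision, code = sample(e$codes, 1))
      })
      tpu <- vapply(yr, function(y) sample(pool_for(y), 1), character(1))
      recs[[length(recs) + 1L]] <- data.frame(
        age = age, sex = truth$sex, year = yr,
        icd_revision = vapply(icd, `[[`, integer(1), "revision"),
        icd_code = vapply(icd, `[[`, character(1), "code"),
        tpu_id = tpu)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(age = integer(0), sex = character(0), year = integer(0),
               icd_revision = integer(0), icd_code = character(0),
               tpu_id = character(0))

  # annual population rows over three TPUs of the matching pool
  pop_rows <- list()
  for (p in seq_len(grid$n_period)) {
    years <- grid$period_start_years[p] + 0:(grid$period_width - 1L)
    for (y in years) {
      pool <- utils::head(pool_for(y), 3L)
      for (a in seq_len(grid$n_age)) {
        annual <- counts$person_years[a, p] / grid$period_width
        pop_rows[[length(pop_rows) + 1L]] <- data.frame(
          age_group = grid$age_lower_edges[a], sex = truth$sex, year = y,
          tpu_id = pool, population = annual / length(pool))
      }
    }
  }
  population <- do.call(rbind, pop_rows)
  list(records = records, population = population, tpu_table = tpu_table,
       counts = counts)
}
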
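# Shared fixtures and independent oracles for the test suite.

quick_mcmc <- function(seed = 1L, n_keep_total = 4000L, n_chains = 2L,
                       burn_in = 1500L, max_burn_in = 12000L,
                       rhat_threshold = 1.05) {
  mcmc_config(n_chains = n_chains, n_keep_total = n_keep_total,
              burn_in = burn_in, max_burn_in = max_burn_in,
              rhat_threshold = rhat_threshold, seed = seed)
}

# one male low-income fit shared by several test files (lazily computed once)
.fixture_env <- new.env(parent = emptyenv())

cached_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    truth <- default_scenario("male", "low")
    counts <- simulate_grid_counts(truth, seed = 101L)
    spec <- apc_model_spec(lexis_grid())
    post <- suppressWarnings(sample_posterior(counts, spec, quick_mcmc(7L)))
    .fixture_env$fit <- list(truth = truth, counts = counts, spec = spec,
                             posterior = post)
  }
  .fixture_env$fit
}

# random unconstrained parameter state on a grid
random_params <- function(grid, sd = 1) {
  apc_parameters(rnorm(1, -8, 2), rnorm(grid$n_age, 0, sd),
                 rnorm(grid$n_period, 0, sd), rnorm(grid$n_cohorts, 0, sd),
                 sigma2 = c(age = 0.01, period = 0.01, cohort = 0.01))
}

# a degenerate posterior whose every retained draw is the given parameter
# state (used to test summaries, DIC and projections without MCMC noise)
degenerate_posterior <- function(params, grid, n_draws = 50L, n_chains = 2L) {
  spec <- apc_model_spec(grid)
  row <- c(params$mu, params$alpha, params$beta, params$gamma,
           params$sigma2["age"], params$sigma2["period"],
           params$sigma2["cohort"])
  nm <- c("mu", sprintf("alpha[%d]", seq_len(grid$n_age)),
          sprintf("beta[%d]", seq_len(grid$n_period)),
          sprintf("gamma[%d]", seq_len(grid$n_cohorts)),
          "sigma2[age]", "sigma2[period]", "sigma2[cohort]")
  draws <- lapply(seq_len(n_chains), function(k) {
    m <- matrix(rep(row, each = n_draws), n_draws, length(row))
    colnames(m) <- nm
    m
  })
  structure(list(draws = draws, spec = spec, grid = grid,
                 config = quick_mcmc(), param_names = nm,
                 rhat = stats::setNames(rep(1, length(nm)), nm),
                 burn_in_used = 0L, converged = TRUE, accept_rate = NULL),
            class = "apc_posterior")
}

# independent constrained Poisson GLM (IRLS) oracle: returns fitted log rates
glm_log_rates <- function(counts, grid) {
  A <- grid$n_age
  P <- grid$n_period
  C <- grid$n_cohorts
  a <- as.vector(row(counts$deaths))
  p <- as.vector(col(counts$deaths))
  ci <- (A - a) + p
  Xa <- matrix(0, length(a), A - 1)
  for (j in seq_len(A - 1)) Xa[, j] <- (a == j) - (a == A)  # mean-zero alpha
  free_b <- setdiff(seq_len(P), c(2L, P - 1L))
  Xb <- vapply(free_b, function(j) as.numeric(p == j), numeric(length(p)))
  rc <- (C + 1L) %/% 2L
  free_c <- setdiff(seq_len(C), rc)
  Xc <- vapply(free_c, function(j) as.numeric(ci == j), numeric(length(p)))
  X <- cbind(1, Xa, Xb, Xc)
  fit <- stats::glm.fit(X, as.vector(counts$deaths), family = stats::poisson(),
                        offset = log(as.vector(counts$person_years)))
  matrix(log(fit$fitted.values / as.vector(counts$person_years)), A, P)
}

# textbook split-chain Rhat by explicit variance decomposition
rhat_oracle <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2
  halves <- cbind(mat[1:half, , drop = FALSE],
                  mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- half / (m - 1) * sum((means - mean(means))^2)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# linear-interpolation (type 7) quantile computed by explicit sorting
sort_quantile <- function(x, probs) {
  x <- sort(x)
  n <- length(x)
  vapply(probs, function(pr) {
    h <- (n - 1) * pr + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}
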
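#' Specification of a (sub)model in the age-period-cohort family
#'
#' Log rates decompose as `mu + alpha[a] + beta[p] + gamma[c]` with
#' `c = cohort_index(a, p)`. Because cohort = period - age, the three effect
#' sets are linearly aliased; identifiable estimates are obtained by fixing
#' the second and penultimate period effects and the central cohort effect
#' to zero (plus a mean-zero constraint on the age effects absorbing the
#' remaining level ambiguity into the intercept). Submodels for DIC
#' comparison are obtained by switching dimensions off.
#'
#' @param grid A [lexis_grid()].
#' @param include_age,include_period,include_cohort Logical; which effect
#'   dimensions the model carries.
#' @param ref_periods Pair of period indices constrained to zero (default
#'   `c(2, n_period - 1)`).
#' @param ref_cohort Cohort index constrained to zero; default the central
#'   cohort `(n_cohorts + 1) / 2` (rounded down for even cohort counts).
#' @param hyper_shape,hyper_rate Gamma hyperprior parameters on each RW2
#'   precision (default the diffuse Gamma(0.001, 0.001) convention).
#' @param mu_prior_var Variance of the diffuse normal prior on the intercept.
#' @return An object of class `apc_model_spec`.
#' @export
apc_model_spec <- function(grid, include_age = TRUE, include_period = TRUE,
                           include_cohort = TRUE,
                           ref_periods = c(2L, grid$n_period - 1L),
                           ref_cohort = (grid$n_cohorts + 1L) %/% 2L,
                           hyper_shape = 0.001, hyper_rate = 0.001,
                           mu_prior_var = 1e6) {
  stopifnot(inherits(grid, "lexis_grid"))
  if (!any(include_age, include_period, include_cohort))
    stop("at least one of age/period/cohort must be included")
  full <- include_age && include_period && include_cohort
  if (full) {
    if (grid$n_period < 3L)
      stop("period reference constraints are degenerate for n_period < 3")
    ref_periods <- sort(as.integer(ref_periods))
    if (length(ref_periods) != 2L || ref_periods[1] == ref_periods[2] ||
        any(ref_periods < 1L) || any(ref_periods > grid$n_period))
      stop("ref_periods must be two distinct in-range period indices")
  }
  ref_cohort <- as.integer(ref_cohort)
  if (ref_cohort < 1L || ref_cohort > grid$n_cohorts)
    stop("ref_cohort out of range")
  structure(list(grid = grid, include_age = include_age,
                 include_period = include_period,
                 include_cohort = include_cohort,
                 ref_periods = as.integer(ref_periods),
                 ref_cohort = ref_cohort,
                 hyper_shape = hyper_shape, hyper_rate = hyper_rate,
                 mu_prior_var = mu_prior_var),
            class = "apc_model_spec")
}

#' Parameter state of the APC model
#'
#' @param mu Intercept on the log-rate (per person-year) scale.
#' @param alpha,beta,gamma Age, period and cohort effect vectors (lengths
#'   `n_age`, `n_period`, `n_cohorts`).
#' @param sigma2 Named numeric of RW2 innovation variances
#'   `c(age = , period = , cohort = )`; entries may be `NA` for excluded
#'   dimensions.
#' @param grid A [lexis_grid()] used for length validation.
#' @return An object of class `apc_parameters`.
#' @export
apc_parameters <- function(mu, alpha, beta, gamma,
                           sigma2 = c(age = NA_real_, period = NA_real_,
                                      cohort = NA_real_),
                           grid = NULL) {
  if (!is.null(grid)) {
    stopifnot(length(alpha) == grid$n_age, length(beta) == grid$n_period,
              length(gamma) == grid$n_cohorts)
  }
  structure(list(mu = as.numeric(mu), alpha = as.numeric(alpha),
                 beta = as.numeric(beta), gamma = as.numeric(gamma),
                 sigma2 = sigma2),
            class = "apc_parameters")
}

#' Log rate for one or all grid cells
#'
#' `eta = mu + alpha[a] + beta[p] + gamma[cohort_index(a, p)]`, with terms
#' omitted for dimensions the model spec excludes.
#'
#' @param params An [apc_parameters()].
#' @param grid A [lexis_grid()].
#' @param age_idx,period_idx Optional cell indices; if omitted the full
#'   `n_age x n_period` matrix of log rates (per person-year) is returned.
#' @param spec Optional [apc_model_spec()] carrying include flags; by default
#'   all three dimensions contribute.
#' @return A scalar (cell given) or matrix of log rates.
#' @export
apc_log_rate <- function(params, grid, age_idx = NULL, period_idx = NULL,
                         spec = NULL) {
  ia <- is.null(spec) || spec$include_age
  ip <- is.null(spec) || spec$include_period
  ic <- is.null(spec) || spec$include_cohort
  if (!is.null(age_idx)) {
    ci <- cohort_index(age_idx, period_idx, grid)
    return(params$mu + (if (ia) params$alpha[age_idx] else 0) +
             (if (ip) params$beta[period_idx] else 0) +
             (if (ic) params$gamma[ci] else 0))
  }
  a <- seq_len(grid$n_age); p <- seq_len(grid$n_period)
  eta <- matrix(params$mu, grid$n_age, grid$n_period)
  if (ia) eta <- eta + params$alpha[a]
  if (ip) eta <- eta + rep(params$beta[p], each = grid$n_age)
  if (ic) {
    ci <- outer(a, p, function(ai, pi) (grid$n_age - ai) + pi)
    eta <- eta + matrix(params$gamma[ci], grid$n_age, grid$n_period)
  }
  eta
}

#' Poisson log likelihood of a parameter state
#'
#' `sum over cells of D*log(N*lambda) - N*lambda - log(D!)` with
#' `lambda = exp(eta)`. Computed on the log scale throughout, so it is finite
#' for all finite parameter values.
#'
#' @param params An [apc_parameters()].
#' @param counts A [stratum_counts()].
#' @param spec Optional [apc_model_spec()] (include flags).
#' @return Scalar log likelihood.
#' @export
apc_loglik <- function(params, counts, spec = NULL) {
  eta <- apc_log_rate(params, counts$grid, spec = spec)
  log_lamN <- log(counts$person_years) + eta
  sum(counts$deaths * log_lamN - exp(log_lamN) - lgamma(counts$deaths + 1))
}

#' RW2 (second-order random walk) log prior
#'
#' Each element from the third onward is normally distributed around the
#' linear extrapolation of its two predecessors:
#' `effects[k] ~ N(2*effects[k-1] - effects[k-2], sigma2)`. The first two
#' elements carry a flat improper prior (contribution zero), so the prior
#' penalizes only second differences — equivalently, it is the joint normal
#' density of the K-2 second differences.
#'
#' @param effects Numeric vector of length >= 3.
#' @param sigma2 Innovation variance (> 0).
#' @return Scalar log density.
#' @export
rw2_logprior <- function(effects, sigma2) {
  if (length(effects) < 3L) stop("need at least 3 effects for an RW2 prior")
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  d2 <- diff(effects, differences = 2L)
  sum(stats::dnorm(d2, mean = 0, sd = sqrt(sigma2), log = TRUE))
}

#' Enforce the identifiability constraints by an affine transform
#'
#' Applies the unique affine re-expression of the parameters that makes
#' `beta[ref1] = beta[ref2] = 0` (removing level and linear trend from the
#' period effects), `gamma[ref_cohort] = 0`, and `mean(alpha) = 0`, absorbing
#' every adjustment into the other effect sets and the intercept via the
#' aliasing identity `c = n_age - a + p`. The fitted log rate of every cell
#' is unchanged. For submodels the excluded dimensions are untouched and each
#' included effect is centred (gamma at its reference, others at their mean).
#'
#' @param params An [apc_parameters()].
#' @param spec An [apc_model_spec()].
#' @return A constrained [apc_parameters()] with identical fitted rates.
#' @export
apply_constraints <- function(params, spec) {
  mu <- params$mu; alpha <- params$alpha
  beta <- params$beta; gamma <- params$gamma
  A <- spec$grid$n_age; P <- spec$grid$n_period; C <- spec$grid$n_cohorts
  if (spec$include_age && spec$include_period && spec$include_cohort) {
    r1 <- spec$ref_periods[1]; r2 <- spec$ref_periods[2]
    v <- (beta[r2] - beta[r1]) / (r2 - r1)
    u <- beta[r1] - v * r1
    beta <- beta - (u + v * seq_len(P))
    # u + v*p = (u - v*A) + v*a + v*c   since p = c - A + a
    mu <- mu + u - v * A
    alpha <- alpha + v * seq_len(A)
    gamma <- gamma + v * seq_len(C)
    g0 <- gamma[spec$ref_cohort]
    gamma <- gamma - g0
    mu <- mu + g0
    m <- mean(alpha)
    alpha <- alpha - m
    mu <- mu + m
  } else {
    if (spec$include_age) {
      m <- mean(alpha); alpha <- alpha - m; mu <- mu + m
    }
    if (spec$include_period) {
      m <- mean(beta); beta <- beta - m; mu <- mu + m
    }
    if (spec$include_cohort) {
      g0 <- gamma[spec$ref_cohort]; gamma <- gamma - g0; mu <- mu + g0
    }
  }
  apc_parameters(mu, alpha, beta, gamma, params$sigma2)
}

#' Split-chain Gelman-Rubin potential scale reduction factor
#'
#' Each chain is split in half, the within-chain variance W and between-chain
#' variance B are formed across the 2m half-chains, and
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)`. Chains that are all constant at
#' the same value are degenerate and reported as 1; chains constant at
#' different values are reported as `Inf` (flagged, never `NaN`).
#'
#' @param chains A `draws x chains` matrix for one scalar parameter, or a
#'   list of per-chain matrices (`draws x parameters`) for many.
#' @return A scalar, or a named vector of Rhat values per parameter.
#' @export
rhat <- function(chains) {
  if (is.list(chains) && !is.data.frame(chains)) {
    npar <- ncol(chains[[1]])
    out <- vapply(seq_len(npar), function(j) {
      rhat(vapply(chains, function(ch) ch[, j], numeric(nrow(chains[[1]]))))
    }, numeric(1))
    names(out) <- colnames(chains[[1]])
    return(out)
  }
  x <- as.matrix(chains)
  n <- nrow(x); m <- ncol(x)
  if (m < 2L || n < 4L) stop("rhat needs >= 2 chains and >= 4 draws each")
  if (all(is.na(x))) return(NA_real_)
  half <- n %/% 2L
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1L):n, , drop = FALSE])
  W <- mean(apply(splits, 2, stats::var))
  B <- half * stats::var(colMeans(splits))
  if (!is.finite(W) || W == 0) {
    if (B == 0 || !is.finite(B)) return(1.0) else return(Inf)
  }
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' MCMC run configuration
#'
#' @param n_chains Number of chains run from distinct over-dispersed initial
#'   values (default 5).
#' @param n_keep_total Total post-burn-in draws retained across chains
#'   (default 40,000; must divide by `n_chains`).
#' @param thin Thinning interval.
#' @param burn_in Initial adaptive burn-in iterations per chain.
#' @param max_burn_in Maximum total burn-in per chain before the run is
#'   declared non-converged.
#' @param rhat_threshold Convergence threshold on the split-chain Rhat of
#'   every monitored parameter (default 1.05).
#' @param seed Integer seed; the entire run (initial values included) is
#'   reproducible from it.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 5L, n_keep_total = 40000L, thin = 1L,
                        burn_in = 2000L, max_burn_in = 20000L,
                        rhat_threshold = 1.05, seed = 1L) {
  stopifnot(n_chains >= 1L, n_keep_total >= n_chains, thin >= 1L,
            burn_in >= 1L, max_burn_in >= burn_in)
  if (n_keep_total %% n_chains != 0L)
    stop("n_keep_total must be divisible by n_chains")
  structure(list(n_chains = as.integer(n_chains),
                 n_keep_total = as.integer(n_keep_total),
                 n_keep_per_chain = as.integer(n_keep_total / n_chains),
                 thin = as.integer(thin), burn_in = as.integer(burn_in),
                 max_burn_in = as.integer(max_burn_in),
                 rhat_threshold = rhat_threshold, seed = as.integer(seed)),
            class = "mcmc_config")
}

.apc_par_names <- function(grid) {
  c("mu",
    sprintf("alpha[%d]", seq_len(grid$n_age)),
    sprintf("beta[%d]", seq_len(grid$n_period)),
    sprintf("gamma[%d]", seq_len(grid$n_cohorts)),
    "sigma2[age]", "sigma2[period]", "sigma2[cohort]")
}

#' Sample the posterior of the APC model by MCMC
#'
#' Runs an adaptive single-site Metropolis-within-Gibbs sampler (random-walk
#' Metropolis on the intercept and effects with per-coordinate adaptive
#' scales frozen after burn-in; conjugate Gibbs draws for the RW2
#' precisions). The identifiability constraints are enforced after every
#' iteration by the deterministic affine transform of
#' [apply_constraints()], so every retained draw satisfies them exactly.
#' After the initial burn-in, sampling windows are drawn and the split-chain
#' Rhat of every monitored parameter is checked; windows are discarded as
#' additional burn-in until all Rhat values fall below the threshold or
#' `max_burn_in` is exhausted, in which case the result is flagged
#' non-converged (never returned silently).
#'
#' @param counts A [stratum_counts()].
#' @param spec An [apc_model_spec()].
#' @param config An [mcmc_config()].
#' @return An object of class `apc_posterior`: per-chain draw matrices,
#'   Rhat per parameter, burn-in used, convergence flag and acceptance
#'   rates. See [dic()], [relative_risks()], [posterior_summary()].
#' @export
sample_posterior <- function(counts, spec, config = mcmc_config()) {
  stopifnot(inherits(counts, "stratum_counts"), inherits(spec, "apc_model_spec"),
            inherits(config, "mcmc_config"))
  grid <- spec$grid
  A <- grid$n_age; P <- grid$n_period; C <- grid$n_cohorts
  D <- as.integer(counts$deaths)
  N <- as.numeric(counts$person_years)
  rp <- if (length(spec$ref_periods) == 2L) spec$ref_periods else c(1L, max(2L, P))

  set.seed(config$seed)
  mu0 <- log((sum(D) + 0.5) / sum(N))
  n_coord <- 1L + A + P + C
  chains_state <- lapply(seq_len(config$n_chains), function(k) {
    list(mu = mu0 + stats::rnorm(1, 0, 0.5),
         alpha = if (spec$include_age) stats::rnorm(A, 0, 0.3) else rep(0, A),
         beta = if (spec$include_period) stats::rnorm(P, 0, 0.3) else rep(0, P),
         gamma = if (spec$include_cohort) stats::rnorm(C, 0, 0.3) else rep(0, C),
         tau_age = 1 / stats::runif(1, 0.01, 0.2),
         tau_period = 1 / stats::runif(1, 0.01, 0.2),
         tau_cohort = 1 / stats::runif(1, 0.01, 0.2))
  })
  scales <- lapply(seq_len(config$n_chains), function(k) rep(log(0.1), n_coord))

  run_chunk <- function(k, n_iter, adapt, adapt_offset, store) {
    .apc_mcmc_chain(D, N, A, P,
                    spec$include_age, spec$include_period, spec$include_cohort,
                    rp[1], rp[2], spec$ref_cohort,
                    spec$hyper_shape, spec$hyper_rate, spec$mu_prior_var,
                    chains_state[[k]], scales[[k]],
                    adapt, adapt_offset, n_iter, config$thin, store)
  }

  # adaptive burn-in
  for (k in seq_len(config$n_chains)) {
    res <- run_chunk(k, config$burn_in, adapt = TRUE, adapt_offset = 0L,
                     store = FALSE)
    chains_state[[k]] <- res$state
    scales[[k]] <- res$log_scales
  }
  burn_used <- config$burn_in
  par_names <- .apc_par_names(grid)
  n_iter_sample <- config$n_keep_per_chain * config$thin

  repeat {
    draws <- vector("list", config$n_chains)
    accept <- vector("list", config$n_chains)
    for (k in seq_len(config$n_chains)) {
      res <- run_chunk(k, n_iter_sample, adapt = FALSE, adapt_offset = 0L,
                       store = TRUE)
      chains_state[[k]] <- res$state
      m <- res$draws
      colnames(m) <- par_names
      draws[[k]] <- m
      accept[[k]] <- res$accept_rate
    }
    rh <- rhat(draws)  # NA for excluded-dimension sigma2 columns (all-NA draws)
    monitored <- rh[!is.na(rh)]
    converged <- all(monitored < config$rhat_threshold)
    if (converged) break
    if (burn_used + n_iter_sample > config$max_burn_in) {
      warning("MCMC did not converge: max Rhat = ",
              signif(max(monitored), 4), " after ", burn_used,
              " burn-in iterations per chain")
      break
    }
    burn_used <- burn_used + n_iter_sample  # discard the window as burn-in
  }

  structure(list(draws = draws, spec = spec, grid = grid, config = config,
                 param_names = par_names, rhat = rh,
                 burn_in_used = burn_used, converged = converged,
                 accept_rate = Reduce(`+`, accept) / length(accept)),
            class = "apc_posterior")
}

#' @export
print.apc_posterior <- function(x, ...) {
  cat(sprintf("apc_posterior: %d chains x %d draws (%sconverged, burn-in %d, max Rhat %.3f)\n",
              length(x$draws), nrow(x$draws[[1]]),
              if (x$converged) "" else "NOT ", x$burn_in_used,
              max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' All retained draws stacked across chains
#'
#' @param posterior An `apc_posterior`.
#' @return A `total_draws x parameters` matrix.
#' @export
as_draws_matrix <- function(posterior) {
  do.call(rbind, posterior$draws)
}

# split a stacked draw row back into parameter blocks
.draw_blocks <- function(grid) {
  A <- grid$n_age; P <- grid$n_period; C <- grid$n_cohorts
  list(mu = 1L, alpha = 1L + seq_len(A), beta = 1L + A + seq_len(P),
       gamma = 1L + A + P + seq_len(C),
       sigma2 = 1L + A + P + C + 1:3)
}

#' Posterior means and 95% credible intervals per parameter
#'
#' @param posterior An `apc_posterior`.
#' @return data.frame with columns `parameter`, `mean`, `lo95`, `hi95`,
#'   `rhat`.
#' @export
posterior_summary <- function(posterior) {
  d <- as_draws_matrix(posterior)
  q <- t(apply(d, 2, function(v) {
    if (all(is.na(v))) return(c(NA_real_, NA_real_, NA_real_))
    c(mean(v), stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7))
  }))
  data.frame(parameter = colnames(d), mean = q[, 1], lo95 = q[, 2],
             hi95 = q[, 3], rhat = unname(posterior$rhat[colnames(d)]),
             row.names = NULL)
}

#' Posterior-mean parameter state
#'
#' @param posterior An `apc_posterior`.
#' @return An [apc_parameters()] at the posterior means.
#' @export
posterior_mean_params <- function(posterior) {
  d <- colMeans(as_draws_matrix(posterior))
  b <- .draw_blocks(posterior$grid)
  apc_parameters(d[b$mu], d[b$alpha], d[b$beta], d[b$gamma],
                 sigma2 = c(age = unname(d[b$sigma2[1]]),
                            period = unname(d[b$sigma2[2]]),
                            cohort = unname(d[b$sigma2[3]])))
}

# deviance without the saturated / lfactorial data constant:
# -2 * sum(D log(N*lambda) - N*lambda). Constant terms cancel in DIC
# differences across models fitted to the same data.
.deviance_cells <- function(eta, D, logN) {
  log_lamN <- logN + eta
  -2 * sum(D * log_lamN - exp(log_lamN))
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance, `pD = Dbar -
#' D(thetabar)` the effective number of parameters, and deviance
#' `-2 sum(D log(N lambda) - N lambda)` (data-only constants omitted
#' consistently, so DIC differences between models on the same data are
#' unaffected; absolute values are not comparable across datasets). Smaller
#' DIC indicates better fit.
#'
#' @param posterior An `apc_posterior`.
#' @param counts The [stratum_counts()] the model was fitted to.
#' @return An object of class `dic_result`: list with `dbar`, `d_at_mean`,
#'   `pd`, `dic`.
#' @export
dic <- function(posterior, counts) {
  grid <- posterior$grid
  d <- as_draws_matrix(posterior)
  b <- .draw_blocks(grid)
  A <- grid$n_age; P <- grid$n_period
  ci <- outer(seq_len(A), seq_len(P), function(a, p) (A - a) + p)
  # cells x effect-draws design: eta = mu + alpha[a] + beta[p] + gamma[c]
  Dv <- as.numeric(counts$deaths)
  logN <- log(as.numeric(counts$person_years))
  a_of <- as.vector(row(matrix(0, A, P)))
  p_of <- as.vector(col(matrix(0, A, P)))
  c_of <- as.vector(ci)
  eff <- cbind(d[, b$mu, drop = FALSE], d[, b$alpha, drop = FALSE],
               d[, b$beta, drop = FALSE], d[, b$gamma, drop = FALSE])
  X <- matrix(0, A * P, ncol(eff))
  X[, 1] <- 1
  X[cbind(seq_len(A * P), 1L + a_of)] <- 1
  X[cbind(seq_len(A * P), 1L + A + p_of)] <- 1
  X[cbind(seq_len(A * P), 1L + A + P + c_of)] <- 1
  etas <- X %*% t(eff)                      # cells x draws
  log_lamN <- logN + etas
  dev_draws <- -2 * colSums(Dv * log_lamN - exp(log_lamN))
  dbar <- mean(dev_draws)
  pm <- posterior_mean_params(posterior)
  eta_bar <- apc_log_rate(pm, grid, spec = posterior$spec)
  d_at_mean <- .deviance_cells(as.numeric(eta_bar), Dv, logN)
  pd <- dbar - d_at_mean
  structure(list(dbar = dbar, d_at_mean = d_at_mean, pd = pd,
                 dic = dbar + pd), class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC = %.2f (Dbar = %.2f, pD = %.2f)\n", x$dic, x$dbar, x$pd))
  invisible(x)
}

#' Relative risks for cohorts and periods
#'
#' `RR = exp(effect)` per draw, summarized by the posterior mean and
#' equal-tailed 95% credible interval. At the reference categories the RR is
#' identically 1 with a zero-width interval.
#'
#' @param posterior An `apc_posterior`.
#' @return List with data.frames `period` and `cohort`, each with columns
#'   `index`, `center_year`, `rr`, `lo95`, `hi95`.
#' @export
relative_risks <- function(posterior) {
  grid <- posterior$grid
  d <- as_draws_matrix(posterior)
  b <- .draw_blocks(grid)
  summarize_rr <- function(cols, centers) {
    rr <- exp(d[, cols, drop = FALSE])
    q <- t(apply(rr, 2, stats::quantile, probs = c(0.025, 0.975),
                 names = FALSE, type = 7))
    data.frame(index = seq_along(cols), center_year = centers,
               rr = colMeans(rr), lo95 = q[, 1], hi95 = q[, 2],
               row.names = NULL)
  }
  list(period = summarize_rr(b$beta, period_centers(grid)),
       cohort = summarize_rr(b$gamma,
                             cohort_center_years(seq_len(grid$n_cohorts), grid)))
}

#' Fitted age-specific rates at the reference period and cohort
#'
#' `exp(mu + alpha[a]) * 100000` per draw (the period and cohort reference
#' effects are zero), summarized by posterior mean and 95% credible interval.
#'
#' @param posterior An `apc_posterior`.
#' @return data.frame with columns `age_lower`, `rate`, `lo95`, `hi95`
#'   (per 100,000 person-years).
#' @export
age_specific_rates <- function(posterior) {
  grid <- posterior$grid
  d <- as_draws_matrix(posterior)
  b <- .draw_blocks(grid)
  rates <- 1e5 * exp(d[, b$mu] + d[, b$alpha, drop = FALSE])
  q <- t(apply(rates, 2, stats::quantile, probs = c(0.025, 0.975),
               names = FALSE, type = 7))
  data.frame(age_lower = grid$age_lower_edges, rate = colMeans(rates),
             lo95 = q[, 1], hi95 = q[, 2], row.names = NULL)
}

#' DIC comparison across the seven age/period/cohort submodels
#'
#' Fits every non-empty combination of the age, period and cohort dimensions
#' to the same counts and tabulates Dbar, pD and DIC.
#'
#' @param counts A [stratum_counts()].
#' @param grid A [lexis_grid()].
#' @param config An [mcmc_config()]; each submodel uses `seed + model index`
#'   so the comparisons are reproducible but not draw-coupled.
#' @param hyper_shape,hyper_rate RW2 precision hyperprior, passed through.
#' @return data.frame `model`, `dbar`, `pd`, `dic`, `converged`, sorted by
#'   DIC.
#' @export
compare_models <- function(counts, grid, config = mcmc_config(),
                           hyper_shape = 0.001, hyper_rate = 0.001) {
  combos <- list(
    age            = c(TRUE, FALSE, FALSE),
    period         = c(FALSE, TRUE, FALSE),
    cohort         = c(FALSE, FALSE, TRUE),
    `age-period`   = c(TRUE, TRUE, FALSE),
    `age-cohort`   = c(TRUE, FALSE, TRUE),
    `period-cohort` = c(FALSE, TRUE, TRUE),
    `age-period-cohort` = c(TRUE, TRUE, TRUE))
  rows <- lapply(seq_along(combos), function(i) {
    inc <- combos[[i]]
    spec <- apc_model_spec(grid, include_age = inc[1], include_period = inc[2],
                           include_cohort = inc[3],
                           hyper_shape = hyper_shape, hyper_rate = hyper_rate)
    cfg <- config
    cfg$seed <- config$seed + i
    post <- sample_posterior(counts, spec, cfg)
    dd <- dic(post, counts)
    data.frame(model = names(combos)[i], dbar = dd$dbar, pd = dd$pd,
               dic = dd$dic, converged = post$converged)
  })
  out <- do.call(rbind, rows)
  out[order(out$dic), ]
}
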
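#' Extend period and cohort effects through the RW2 predictive distribution
#'
#' For each retained posterior draw and each step ahead, the new effect is
#' the linear extrapolation of its two predecessors plus a Gaussian
#' innovation with that draw's own RW2 variance:
#' `new = 2*prev - prev2 + e`, `e ~ N(0, sigma2_draw)`. Using per-draw
#' variances propagates hyperparameter uncertainty; sampled (not conditional
#' mean) future effects give genuine predictive intervals. With
#' `sigma2 = 0` the extension is the exact deterministic linear
#' extrapolation.
#'
#' @param posterior An `apc_posterior` from the full age-period-cohort model.
#' @param n_ahead Number of future periods (and cohorts) to extend; >= 1.
#' @param seed Integer seed for the innovation draws.
#' @return An object of class `apc_extension`: matrices `beta`
#'   (`draws x (n_period + n_ahead)`) and `gamma`
#'   (`draws x (n_cohorts + n_ahead)`) whose observed-window columns equal
#'   the fitted posterior draws exactly, plus `n_ahead`.
#' @export
extend_effects <- function(posterior, n_ahead = 3L, seed = 1L) {
  stopifnot(inherits(posterior, "apc_posterior"))
  if (n_ahead < 1L) stop("n_ahead must be >= 1")
  spec <- posterior$spec
  if (!(spec$include_period && spec$include_cohort))
    stop("projection requires a model with period and cohort effects")
  grid <- posterior$grid
  d <- as_draws_matrix(posterior)
  b <- .draw_blocks(grid)
  nd <- nrow(d)
  s2_b <- d[, b$sigma2[2]]
  s2_g <- d[, b$sigma2[3]]
  set.seed(seed)
  extend <- function(obs, s2) {
    ext <- cbind(obs, matrix(NA_real_, nd, n_ahead))
    K <- ncol(obs)
    for (j in seq_len(n_ahead)) {
      eps <- stats::rnorm(nd, 0, sqrt(s2))
      ext[, K + j] <- 2 * ext[, K + j - 1] - ext[, K + j - 2] + eps
    }
    ext
  }
  structure(list(beta = extend(d[, b$beta, drop = FALSE], s2_b),
                 gamma = extend(d[, b$gamma, drop = FALSE], s2_g),
                 n_ahead = as.integer(n_ahead)),
            class = "apc_extension")
}

#' Projected age-specific rate draws for future periods
#'
#' For future period `p'` and age group `a` the rate per 100,000 is
#' `1e5 * exp(mu + alpha[a] + beta_ext[p'] + gamma_ext[cohort_index(a, p')])`.
#' The youngest age group in the last projected period reaches cohort
#' `n_cohorts + n_ahead`, so all extrapolated cohort effects are consumed; a
#' missing extended cohort is an error (guarding the off-by-one between
#' projected periods and cohorts).
#'
#' @param posterior An `apc_posterior`.
#' @param extension An [extend_effects()] result aligned with the posterior
#'   draws.
#' @param grid A [lexis_grid()] (defaults to the posterior's grid).
#' @return A `draws x n_age x n_ahead` array of rates per 100,000.
#' @export
project_rates <- function(posterior, extension, grid = posterior$grid) {
  stopifnot(inherits(extension, "apc_extension"))
  d <- as_draws_matrix(posterior)
  b <- .draw_blocks(grid)
  nd <- nrow(d)
  if (nrow(extension$beta) != nd)
    stop("extension is not aligned with the posterior draws")
  A <- grid$n_age; P <- grid$n_period
  n_ahead <- extension$n_ahead
  need_c <- cohort_index(1L, P + n_ahead, grid)
  if (ncol(extension$gamma) < need_c)
    stop("extended cohort effects end at ", ncol(extension$gamma),
         " but cohort ", need_c, " is required for the projection diagonal")
  out <- array(NA_real_, dim = c(nd, A, n_ahead))
  mu <- d[, b$mu]
  for (j in seq_len(n_ahead)) {
    p <- P + j
    for (a in seq_len(A)) {
      ci <- cohort_index(a, p, grid)
      out[, a, j] <- 1e5 * exp(mu + d[, b$alpha[a]] +
                                 extension$beta[, p] + extension$gamma[, ci])
    }
  }
  out
}

.period_label <- function(start, width) paste0(start, "-", start + width - 1L)

#' Age-standardized rate series over observed and projected periods
#'
#' Observed periods use the fitted age-specific rates per draw; future
#' periods use the projected rate draws. Each period's ASR draws are
#' summarized by the posterior mean and equal-tailed 95% credible interval.
#'
#' @param posterior An `apc_posterior`.
#' @param extension An [extend_effects()] result.
#' @param std A `standard_population` restricted to the grid (see
#'   [restrict_weights()]); defaults to the WHO standard restricted to the
#'   posterior's grid.
#' @return data.frame of class `asr_series` with columns `period_index`,
#'   `period`, `center_year`, `asr` (posterior mean), `asr_med` (posterior
#'   median, stabler for far projections), `asr_lo`, `asr_hi`,
#'   `observed_or_projected`.
#' @export
asr_projection_series <- function(posterior, extension,
                                  std = restrict_weights(who_standard(),
                                                         posterior$grid)) {
  grid <- posterior$grid
  d <- as_draws_matrix(posterior)
  b <- .draw_blocks(grid)
  A <- grid$n_age; P <- grid$n_period
  n_ahead <- extension$n_ahead
  rows <- vector("list", P + n_ahead)
  alpha <- d[, b$alpha, drop = FALSE]
  mu <- d[, b$mu]
  for (p in seq_len(P)) {
    rates <- matrix(NA_real_, nrow(d), A)
    for (a in seq_len(A)) {
      ci <- cohort_index(a, p, grid)
      rates[, a] <- 1e5 * exp(mu + alpha[, a] + d[, b$beta[p]] + d[, b$gamma[ci]])
    }
    s <- asr_from_draws(rates, std)
    rows[[p]] <- data.frame(period_index = p,
                            period = .period_label(grid$period_start_years[p],
                                                   grid$period_width),
                            center_year = period_centers(grid)[p],
                            asr = s["mean"], asr_med = s["med"],
                            asr_lo = s["lo95"], asr_hi = s["hi95"],
                            observed_or_projected = "observed")
  }
  proj <- project_rates(posterior, extension, grid)
  for (j in seq_len(n_ahead)) {
    s <- asr_from_draws(proj[, , j], std)
    start <- grid$period_start_years[P] + j * grid$period_width
    rows[[P + j]] <- data.frame(period_index = P + j,
                                period = .period_label(start, grid$period_width),
                                center_year = start + (grid$period_width - 1L) %/% 2L,
                                asr = s["mean"], asr_med = s["med"],
                                asr_lo = s["lo95"], asr_hi = s["hi95"],
                                observed_or_projected = "projected")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("asr_series", "data.frame")
  out
}

#' Fit-and-project convenience wrapper
#'
#' @param posterior An `apc_posterior`.
#' @param n_ahead Projection horizon in periods (default 3: 2006-2010,
#'   2011-2015, 2016-2020 on the default grid).
#' @param seed Seed for the predictive innovations.
#' @param std Standard population (restricted to the grid).
#' @return List of class `projection_result` with `extension`,
#'   `projected_rates` (draws x age x period array) and `asr_series`.
#' @export
project_mortality <- function(posterior, n_ahead = 3L, seed = 1L,
                              std = restrict_weights(who_standard(),
                                                     posterior$grid)) {
  ext <- extend_effects(posterior, n_ahead = n_ahead, seed = seed)
  rates <- project_rates(posterior, ext)
  series <- asr_projection_series(posterior, ext, std)
  structure(list(extension = ext, projected_rates = rates,
                 asr_series = series), class = "projection_result")
}
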
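#' WHO World Standard Population age weights
#'
#' The WHO World Standard (Ahmad et al. 2001, GPE Discussion Paper 31) age
#' distribution in 5-year groups 0-4 ... 80-84 plus 85+, as percentages of
#' the standard population. The published 85-89/90-94/95-99/100+ tail
#' (0.44, 0.15, 0.04, 0.005) is collapsed into a single 85+ group here.
#' Weights are renormalized to sum to one.
#'
#' @return A `standard_population`: data.frame with `age_lower` and `weight`
#'   columns (weights summing to 1) and a `label` attribute.
#' @export
who_standard <- function() {
  age_lower <- seq(0L, 85L, by = 5L)
  pct <- c(8.86, 8.69, 8.60, 8.47, 8.22, 7.93, 7.61, 7.15, 6.59, 6.04,
           5.37, 4.55, 3.72, 2.96, 2.21, 1.52, 0.91, 0.635)
  std <- data.frame(age_lower = age_lower, weight = pct / sum(pct))
  attr(std, "label") <- "WHO World Standard"
  class(std) <- c("standard_population", "data.frame")
  std
}

#' Restrict and renormalize a standard population to a Lexis grid
#'
#' Weights below the grid's first age group are dropped; weights at or above
#' the open-ended top group's lower edge are collapsed into the top group.
#' The result is renormalized to sum to one, so age-standardized rates over
#' the restricted range are "30+ ASRs" on the default grid.
#'
#' @param full_standard A `standard_population`, e.g. [who_standard()].
#' @param grid A [lexis_grid()].
#' @return A `standard_population` with one weight per grid age group.
#' @export
restrict_weights <- function(full_standard, grid) {
  stopifnot(inherits(full_standard, "standard_population"))
  w <- rep(0, grid$n_age)
  top <- grid$age_lower_edges[grid$n_age]
  for (i in seq_len(nrow(full_standard))) {
    a <- full_standard$age_lower[i]
    if (a < grid$age_lower_edges[1]) next
    idx <- if (grid$open_ended_top && a >= top) grid$n_age
           else match(a, grid$age_lower_edges)
    if (is.na(idx)) stop("standard age group starting at ", a,
                         " does not align with the grid")
    w[idx] <- w[idx] + full_standard$weight[i]
  }
  if (any(w == 0)) stop("grid age group(s) not covered by the standard: ",
                        paste(grid$age_lower_edges[w == 0], collapse = ", "))
  std <- data.frame(age_lower = grid$age_lower_edges, weight = w / sum(w))
  attr(std, "label") <- paste0(attr(full_standard, "label"), " (restricted ",
                               grid$age_lower_edges[1], "+)")
  class(std) <- c("standard_population", "data.frame")
  std
}

#' Directly age-standardized rate
#'
#' The weighted average `sum(w_a * rate_a)` of age-specific rates using the
#' standard population's (normalized) age weights: a convex combination, so
#' the result always lies between the smallest and largest age-specific rate.
#'
#' @param age_rates Numeric vector, one rate (per 100,000 person-years) per
#'   grid age group.
#' @param std A `standard_population` whose weights match `age_rates` in
#'   length and order.
#' @return The age-standardized rate per 100,000.
#' @export
direct_asr <- function(age_rates, std) {
  stopifnot(inherits(std, "standard_population"))
  if (length(age_rates) != nrow(std))
    stop("length(age_rates) must equal the number of standard weights")
  sum(std$weight * age_rates)
}

#' Posterior summary of the age-standardized rate from rate draws
#'
#' Computes the ASR for every posterior draw of the age-specific rates, then
#' summarizes across draws by the mean and the equal-tailed 95% credible
#' interval (2.5% and 97.5% empirical quantiles, linear-interpolation
#' definition).
#'
#' @param rate_draws `draws x n_age` matrix of age-specific rates per
#'   100,000.
#' @param std A `standard_population` matching the columns.
#' @return Named numeric vector `c(mean, med, lo95, hi95)`. The median is
#'   carried alongside the mean because far-horizon projected rates are
#'   log-normal-like and their posterior mean can be dominated by a few
#'   extreme draws.
#' @export
asr_from_draws <- function(rate_draws, std) {
  rate_draws <- as.matrix(rate_draws)
  if (nrow(rate_draws) < 2L) stop("need at least 2 draws")
  if (ncol(rate_draws) != nrow(std))
    stop("rate_draws columns must match the standard weights")
  asr <- as.vector(rate_draws %*% std$weight)
  q <- stats::quantile(asr, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  c(mean = mean(asr), med = q[2], lo95 = q[1], hi95 = q[3])
}
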
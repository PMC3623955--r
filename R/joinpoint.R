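#' Continuous piecewise-linear fit with fixed joinpoints
#'
#' Least-squares fit of `y` on the continuous broken-line basis
#' `{1, x, (x - tau_j)_+}` for the given joinpoint positions: exact linear
#' algebra, no iteration. The fitted function is continuous at every
#' joinpoint; segment slopes are the cumulative sums of the slope changes.
#'
#' @param x Ordered numeric predictor (typically effect-series centre years).
#' @param y Response (typically posterior-mean log relative risks).
#' @param positions Joinpoint x-values, strictly inside `(min(x), max(x))`.
#' @param min_obs Minimum number of observations per induced segment
#'   (segments are `x <= tau_1`, `tau_j < x <= tau_{j+1}`, `x > tau_k`).
#' @return Object of class `joinpoint_fit`: `n_joinpoints`,
#'   `joinpoint_positions`, `intercept`, `segment_slopes`, `fitted`, `sse`,
#'   `bic`.
#' @export
fit_fixed_joinpoints <- function(x, y, positions = numeric(0), min_obs = 2L) {
  stopifnot(length(x) == length(y), !is.unsorted(x))
  n <- length(x)
  positions <- sort(as.numeric(positions))
  if (anyDuplicated(positions))
    stop("duplicate joinpoint positions give an ill-conditioned basis")
  if (length(positions) &&
      (min(positions) <= min(x) || max(positions) >= max(x)))
    stop("joinpoint positions must lie strictly inside (min(x), max(x))")
  seg <- findInterval(x, positions, left.open = TRUE)  # 0..k segment id
  cnt <- tabulate(seg + 1L, nbins = length(positions) + 1L)
  if (any(cnt < min_obs))
    stop("each segment must contain at least ", min_obs, " observations")
  X <- cbind(1, x)
  for (tau in positions) X <- cbind(X, pmax(x - tau, 0))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("ill-conditioned joinpoint basis")
  coef <- qr.coef(qrX, y)
  fitted <- as.vector(X %*% coef)
  sse <- sum((y - fitted)^2)
  # an SSE at rounding-error level is an exact fit: map it to zero so its
  # BIC is -Inf rather than an arbitrary large negative number
  if (sse < 1e-16 * max(sum((y - mean(y))^2), 1)) sse <- 0
  k <- length(positions)
  structure(list(n_joinpoints = k,
                 joinpoint_positions = positions,
                 intercept = unname(coef[1]),
                 segment_slopes = unname(cumsum(coef[-1])),
                 coefficients = unname(coef),
                 fitted = fitted, sse = sse,
                 bic = .joinpoint_bic(sse, n, k)),
            class = "joinpoint_fit")
}

# BIC_k = n log(SSE/n) + p_k log(n); p_k = 2 + 2k counts intercept, slope and
# per joinpoint a position plus a slope change. SSE = 0 maps to -Inf.
.joinpoint_bic <- function(sse, n, k) {
  if (sse <= 0) return(-Inf)
  n * log(sse / n) + (2 + 2 * k) * log(n)
}

#' @export
print.joinpoint_fit <- function(x, ...) {
  cat(sprintf("joinpoint fit: %d joinpoint(s)%s; slopes %s; SSE %.4g; BIC %.3f\n",
              x$n_joinpoints,
              if (x$n_joinpoints) paste0(" at ",
                                         paste(x$joinpoint_positions, collapse = ", ")) else "",
              paste(signif(x$segment_slopes, 4), collapse = ", "),
              x$sse, x$bic))
  invisible(x)
}

#' Exhaustive grid search for the best joinpoints at each model size
#'
#' For each `k` in `0:max_k`, enumerates all combinations of `k` candidate
#' positions (by default the observed interior x-values) and returns the
#' SSE-minimal fit. `max_k` is reduced with a warning when the minimum-
#' observations-per-segment constraint makes larger models infeasible.
#'
#' @param x,y As in [fit_fixed_joinpoints()].
#' @param max_k Maximum number of joinpoints considered.
#' @param candidate_grid Candidate positions (default: interior observed x).
#' @param min_obs Minimum observations per segment.
#' @return List of `joinpoint_fit` objects indexed `k0`, `k1`, ...
#' @export
search_joinpoints <- function(x, y, max_k = 3L,
                              candidate_grid = x[-c(1L, length(x))],
                              min_obs = 2L) {
  stopifnot(length(x) == length(y), length(x) >= 2L * min_obs)
  candidate_grid <- sort(unique(candidate_grid))
  candidate_grid <- candidate_grid[candidate_grid > min(x) &
                                     candidate_grid < max(x)]
  # largest k for which segments of min_obs points can exist at all
  k_feasible <- max(0L, length(x) %/% min_obs - 1L)
  if (max_k > k_feasible) {
    warning("max_k reduced from ", max_k, " to ", k_feasible,
            " by the min_obs constraint")
    max_k <- k_feasible
  }
  fits <- list(k0 = fit_fixed_joinpoints(x, y, numeric(0), min_obs))
  for (k in seq_len(max_k)) {
    if (length(candidate_grid) < k) break
    combos <- utils::combn(candidate_grid, k, simplify = FALSE)
    best <- NULL
    for (pos in combos) {
      f <- tryCatch(fit_fixed_joinpoints(x, y, pos, min_obs),
                    error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$sse < best$sse)) best <- f
    }
    if (is.null(best)) break
    fits[[paste0("k", k)]] <- best
  }
  fits
}

#' Select the joinpoint model with the smallest BIC
#'
#' `BIC_k = n log(SSE_k / n) + (2 + 2k) log(n)`. Ties (including multiple
#' zero-SSE fits, whose BIC is `-Inf`) resolve to the smaller `k`.
#'
#' @param fits List of `joinpoint_fit`s from [search_joinpoints()] sharing
#'   the same data.
#' @param n Number of observations the fits share.
#' @return The selected `joinpoint_fit`.
#' @export
select_by_bic <- function(fits, n) {
  ks <- vapply(fits, function(f) f$n_joinpoints, integer(1))
  fits <- fits[order(ks)]
  bics <- vapply(fits, function(f) .joinpoint_bic(f$sse, n, f$n_joinpoints),
                 numeric(1))
  fits[[which.min(bics)]]  # first minimum = smallest k on ties (incl. -Inf)
}

#' Joinpoint regression of a trend series
#'
#' Convenience wrapper: exhaustive search per model size followed by BIC
#' selection. Intended for posterior-mean cohort or period log relative
#' risks, to locate changes in linear trend.
#'
#' @param x,y,max_k,candidate_grid,min_obs As in [search_joinpoints()].
#' @return The BIC-selected `joinpoint_fit`, with the per-k fits attached as
#'   attribute `fits`.
#' @export
joinpoint <- function(x, y, max_k = 3L, candidate_grid = x[-c(1L, length(x))],
                      min_obs = 2L) {
  fits <- search_joinpoints(x, y, max_k, candidate_grid, min_obs)
  best <- select_by_bic(fits, length(x))
  attr(best, "fits") <- fits
  best
}
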
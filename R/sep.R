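#' Classify neighbourhoods into income strata by per-census median split
#'
#' Within each census year the cutoff is the median of that year's TPU
#' (Tertiary Planning Unit) median household incomes per capita, unweighted
#' across TPUs. A TPU with income strictly below the cutoff is `"low"`;
#' income equal to or above the cutoff is `"high"`. With an even number of
#' TPUs the cutoff is the lower of the two middle order statistics, so at
#' least one TPU always sits exactly at the cutoff and is labelled high,
#' keeping the "equal to or above" rule non-vacuous.
#'
#' The split is relative within each census year (a different cut point each
#' year), so it is invariant to rescaling all of a year's incomes by a
#' positive constant.
#'
#' @param table data.frame with columns `tpu_id`, `census_year`,
#'   `median_income_per_capita` (positive). Rows with missing income are left
#'   unassigned and reported via the `unassigned` attribute.
#' @return A data.frame of class `sep_assignment` with columns `tpu_id`,
#'   `census_year`, `income_group`, `cutoff`.
#' @examples
#' tab <- data.frame(tpu_id = c("a", "b", "c"), census_year = 1981,
#'                   median_income_per_capita = c(100, 200, 300))
#' classify_tpus(tab)  # cutoff 200; "b" is high
#' @export
classify_tpus <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("tpu_id", "census_year", "median_income_per_capita") %in% names(table)))
  ok <- !is.na(table$median_income_per_capita)
  unassigned <- table[!ok, c("tpu_id", "census_year")]
  tab <- table[ok, , drop = FALSE]
  out <- do.call(rbind, lapply(split(tab, tab$census_year), function(d) {
    if (nrow(d) < 2L)
      stop("need at least 2 TPUs per census year (year ", d$census_year[1], ")")
    x <- sort(d$median_income_per_capita)
    cutoff <- x[floor((length(x) + 1) / 2)]  # lower-middle for even counts
    data.frame(tpu_id = d$tpu_id,
               census_year = d$census_year,
               income_group = ifelse(d$median_income_per_capita < cutoff, "low", "high"),
               cutoff = cutoff)
  }))
  rownames(out) <- NULL
  attr(out, "unassigned") <- unassigned
  class(out) <- c("sep_assignment", "data.frame")
  out
}

#' Census year nearest to a calendar year
#'
#' Ties between two equally near census years resolve to the earlier one.
#'
#' @param year Calendar year(s).
#' @param census_years Available census years.
#' @return The chosen census year per input year.
#' @export
nearest_census <- function(year, census_years) {
  cy <- sort(unique(census_years))
  vapply(year, function(y) {
    d <- abs(cy - y)
    cy[which.min(d)]  # which.min takes the first (earlier) on ties
  }, numeric(1))
}

#' Income stratum of a record given its TPU and year
#'
#' Uses the SEP assignment of the census year nearest to the record's year
#' (earlier year on ties) — deaths and population are classified by the
#' income of their TPU of residence at the time of the record.
#'
#' @param record_year Calendar year(s) of the records.
#' @param tpu_id TPU identifier(s), recycled against `record_year`.
#' @param assignment A `sep_assignment` from [classify_tpus()].
#' @return Character vector `"low"`/`"high"`, `NA` where the TPU is unknown
#'   in the chosen census (reported via the `n_unassigned` attribute).
#' @export
stratum_of <- function(record_year, tpu_id, assignment) {
  stopifnot(inherits(assignment, "sep_assignment"))
  n <- max(length(record_year), length(tpu_id))
  record_year <- rep_len(record_year, n)
  tpu_id <- rep_len(as.character(tpu_id), n)
  census <- nearest_census(record_year, assignment$census_year)
  key <- paste(tpu_id, census, sep = "\r")
  lut <- assignment$income_group
  names(lut) <- paste(assignment$tpu_id, assignment$census_year, sep = "\r")
  out <- unname(lut[key])
  attr(out, "n_unassigned") <- sum(is.na(out))
  out
}
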
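#' Age-period (Lexis) grid
#'
#' Defines the rectangular age x period discretization on which deaths and
#' person-years are tabulated. Birth cohorts run along the grid diagonals:
#' an A x P grid carries A + P - 1 overlapping cohorts, each spanning twice
#' the age-group width.
#'
#' @param age_start Lower edge (years) of the youngest age group.
#' @param n_age Number of age groups.
#' @param age_width Width of each age group in years.
#' @param period_start First calendar year of the earliest period.
#' @param n_period Number of calendar periods.
#' @param period_width Width of each period in years. Must equal `age_width`
#'   for the diagonal cohort structure to hold.
#' @param open_ended_top If `TRUE` the last age group is open-ended
#'   ("75 or above" on the default grid).
#'
#' @return An object of class `lexis_grid`.
#' @examples
#' g <- lexis_grid()            # 10 age groups 30-34 ... 75+, 6 periods 1976-2005
#' g$n_cohorts                  # 15
#' @export
lexis_grid <- function(age_start = 30L, n_age = 10L, age_width = 5L,
                       period_start = 1976L, n_period = 6L, period_width = 5L,
                       open_ended_top = TRUE) {
  stopifnot(n_age >= 2L, n_period >= 1L, age_width >= 1L,
            period_width == age_width)
  age_lower <- age_start + age_width * (seq_len(n_age) - 1L)
  period_lower <- period_start + period_width * (seq_len(n_period) - 1L)
  g <- structure(list(
    age_lower_edges   = as.integer(age_lower),
    age_width         = as.integer(age_width),
    open_ended_top    = isTRUE(open_ended_top),
    period_start_years = as.integer(period_lower),
    period_width      = as.integer(period_width),
    n_age             = as.integer(n_age),
    n_period          = as.integer(n_period),
    n_cohorts         = as.integer(n_age + n_period - 1L)
  ), class = "lexis_grid")
  g
}

#' @export
print.lexis_grid <- function(x, ...) {
  top <- if (x$open_ended_top) paste0(max(x$age_lower_edges), "+") else
    paste0(max(x$age_lower_edges), "-", max(x$age_lower_edges) + x$age_width - 1L)
  cat(sprintf("Lexis grid: %d age groups (%d-%d ... %s), %d periods (%d-%d ... %d-%d), %d cohorts\n",
              x$n_age, x$age_lower_edges[1], x$age_lower_edges[1] + x$age_width - 1L, top,
              x$n_period, x$period_start_years[1],
              x$period_start_years[1] + x$period_width - 1L,
              max(x$period_start_years),
              max(x$period_start_years) + x$period_width - 1L,
              x$n_cohorts))
  invisible(x)
}

#' Mid-points of age groups and periods
#'
#' The open-ended top age group uses a nominal centre of its lower edge plus
#' half the group width beyond one width (77.5 on the default 75+ group).
#'
#' @param grid A [lexis_grid()].
#' @return Numeric vector of centres.
#' @export
age_centers <- function(grid) {
  # centre of [L, L+w) is L + w/2; the open top group takes the same nominal
  # centre (77.5 for the default 75+ group)
  grid$age_lower_edges + grid$age_width / 2
}

#' @rdname age_centers
#' @export
period_centers <- function(grid) {
  # middle calendar year of each period (1978 for 1976-1980, ..., 2018 for
  # 2016-2020): the usual labelling convention for 5-year periods
  grid$period_start_years + (grid$period_width - 1L) %/% 2L
}

#' Cohort index of a grid cell
#'
#' Birth cohort = period of death minus age at death, so cohorts are the
#' anti-diagonals of the age x period grid. With 1-based indices the cohort
#' index is `(n_age - age_idx) + period_idx`: the oldest-age, earliest-period
#' cell is cohort 1 and the youngest-age, latest-period cell is cohort
#' `n_age + n_period - 1`. `period_idx` may exceed `n_period`, which is how
#' projected periods address the extrapolated cohorts.
#'
#' @param age_idx 1-based age-group index (scalar or vector).
#' @param period_idx 1-based period index; values beyond `n_period` are
#'   allowed (projection cells).
#' @param grid A [lexis_grid()].
#' @return Integer cohort index (1-based), vectorized over the inputs.
#' @examples
#' g <- lexis_grid()
#' cohort_index(10, 1, g)  # 1: oldest age, earliest period
#' cohort_index(1, 6, g)   # 15
#' cohort_index(1, 9, g)   # 18: projection cell three periods ahead
#' @export
cohort_index <- function(age_idx, period_idx, grid) {
  age_idx <- as.integer(age_idx); period_idx <- as.integer(period_idx)
  if (any(is.na(age_idx)) || any(age_idx < 1L) || any(age_idx > grid$n_age))
    stop("age_idx out of range [1, ", grid$n_age, "]")
  if (any(is.na(period_idx)) || any(period_idx < 1L))
    stop("period_idx must be >= 1")
  (grid$n_age - age_idx) + period_idx
}

#' Cohort labels: centre years and 10-year spans
#'
#' Cohort centre = (period centre) - (age-group centre), rounded half-up to
#' the nearest year; consecutive centres differ by the grid width. On the
#' default grid cohort 1 is centred on 1901, the central cohort (8) on 1936
#' and cohort 15 on 1971. Spans are centre +/- one group width (overlapping
#' 10-year cohorts on a 5-year grid). Indices beyond `n_cohorts` label
#' projected cohorts.
#'
#' @param index Cohort index (vectorized).
#' @param grid A [lexis_grid()].
#' @return A data.frame with columns `index`, `center_year`, `span_start`,
#'   `span_end`.
#' @export
cohort_label <- function(index, grid) {
  index <- as.integer(index)
  if (any(index < 1L)) stop("cohort index must be >= 1")
  # centre for cohort c from any regular diagonal cell:
  # period_center(p) - age_center(a) with c = n_age - a + p
  base <- (grid$period_start_years[1] + (grid$period_width - 1L) %/% 2L) -
    (grid$age_lower_edges[grid$n_age] + grid$age_width / 2)   # cohort 1 centre
  ctr <- base + grid$age_width * (index - 1L)
  ctr <- floor(ctr + 0.5)  # round half-up to nearest year
  # span is centre +/- age_width: overlapping 10-year cohorts on the 5-year grid
  data.frame(index = index,
             center_year = as.integer(ctr),
             span_start = as.integer(ctr - grid$age_width),
             span_end = as.integer(ctr + grid$age_width))
}

#' @rdname cohort_label
#' @export
cohort_center_years <- function(index, grid) cohort_label(index, grid)$center_year

#' Classify ICD codes as ischaemic heart disease
#'
#' IHD is ICD-8 410-414, ICD-9 410-414 and ICD-10 I20-I25. Codes are matched
#' on their leading rubric after stripping punctuation, so decimal subcodes
#' ("414.9", "I21.4") inherit the parent rubric's status. Unparseable codes
#' yield `NA` (flagged invalid), never a silent `FALSE`.
#'
#' @param icd_code Character vector of ICD codes.
#' @param icd_revision Integer vector (8, 9 or 10), recycled.
#' @return Logical vector; `NA` where the code cannot be parsed under its
#'   revision.
#' @examples
#' is_ihd("4149", 9)    # TRUE (rubric 414)
#' is_ihd("I21.9", 10)  # TRUE
#' is_ihd("I26", 10)    # FALSE
#' @export
is_ihd <- function(icd_code, icd_revision) {
  n <- max(length(icd_code), length(icd_revision))
  code <- rep_len(toupper(trimws(as.character(icd_code))), n)
  rev <- rep_len(as.integer(icd_revision), n)
  code <- gsub("[^A-Z0-9]", "", code)
  out <- rep(NA, n)
  num <- rev %in% c(8L, 9L)
  ok_num <- num & grepl("^[0-9]{3}", code)
  rub <- suppressWarnings(as.integer(substr(code[ok_num], 1L, 3L)))
  out[ok_num] <- rub >= 410L & rub <= 414L
  i10 <- rev == 10L
  ok_10 <- i10 & grepl("^[A-Z][0-9]{2}", code)
  letter <- substr(code[ok_10], 1L, 1L)
  rub10 <- suppressWarnings(as.integer(substr(code[ok_10], 2L, 3L)))
  out[ok_10] <- letter == "I" & rub10 >= 20L & rub10 <= 25L
  bad_rev <- !(rev %in% c(8L, 9L, 10L))
  out[bad_rev] <- NA
  as.logical(out)
}

#' Deaths and person-years for one sex x income stratum
#'
#' @param grid A [lexis_grid()].
#' @param sex `"female"` or `"male"`.
#' @param income_group `"low"` or `"high"`.
#' @param deaths `n_age x n_period` matrix of non-negative integer counts.
#' @param person_years `n_age x n_period` matrix of positive person-years
#'   (annual population summed over the period's years).
#' @return An object of class `stratum_counts`.
#' @export
stratum_counts <- function(grid, sex, income_group, deaths, person_years) {
  sex <- match.arg(sex, c("female", "male"))
  income_group <- match.arg(income_group, c("low", "high"))
  deaths <- as.matrix(deaths); person_years <- as.matrix(person_years)
  if (!all(dim(deaths) == c(grid$n_age, grid$n_period)))
    stop("deaths must be n_age x n_period (", grid$n_age, " x ", grid$n_period, ")")
  if (!all(dim(person_years) == dim(deaths)))
    stop("person_years must have the same shape as deaths")
  if (any(deaths < 0) || any(deaths != round(deaths)))
    stop("deaths must be non-negative integers")
  if (any(person_years <= 0))
    stop("every person_years cell must be positive")
  structure(list(grid = grid, sex = sex, income_group = income_group,
                 deaths = deaths, person_years = person_years),
            class = "stratum_counts")
}

#' @export
print.stratum_counts <- function(x, ...) {
  cat(sprintf("stratum_counts: %s / %s income; %d deaths over %d cells\n",
              x$sex, x$income_group, sum(x$deaths),
              length(x$deaths)))
  invisible(x)
}

#' Crude age- and period-specific mortality rates
#'
#' @param counts A [stratum_counts()].
#' @return `n_age x n_period` matrix of rates per 100,000 person-years.
#' @export
crude_rates <- function(counts) {
  stopifnot(inherits(counts, "stratum_counts"))
  1e5 * counts$deaths / counts$person_years
}

# --- record-level aggregation --------------------------------------------

# map ages/years to grid indices; NA when outside
.age_idx_of <- function(age, grid) {
  idx <- findInterval(age, grid$age_lower_edges)
  idx[age < grid$age_lower_edges[1]] <- NA_integer_
  if (!grid$open_ended_top) {
    top <- grid$age_lower_edges[grid$n_age] + grid$age_width
    idx[age >= top] <- NA_integer_
  }
  as.integer(idx)
}

.period_idx_of <- function(year, grid) {
  idx <- findInterval(year, grid$period_start_years)
  top <- grid$period_start_years[grid$n_period] + grid$period_width
  idx[year < grid$period_start_years[1] | year >= top] <- NA_integer_
  as.integer(idx)
}

#' Aggregate individual death records onto a stratified Lexis grid
#'
#' Records are expected to be pre-filtered to the cause of interest (see
#' [is_ihd()] and [filter_ihd()]). Each retained record increments exactly
#' one cell of one sex x income stratum. Records are dropped, with a reported
#' tally (never silently), when the age is below the grid (ages under 30 on
#' the default grid), the year falls outside all periods, or the TPU cannot
#' be assigned an income group.
#'
#' @param records data.frame with columns `age`, `sex`, `year`, `tpu_id`.
#' @param grid A [lexis_grid()].
#' @param assignment A `sep_assignment` from [classify_tpus()] used to map
#'   each record's TPU (at its year of death) to an income group, or `NULL`
#'   if `records` already has an `income_group` column.
#' @return A list with `deaths` (named list of `n_age x n_period` matrices,
#'   one per `"<sex>.<income>"` stratum), `retained`, and `dropped`
#'   (data.frame of reason/count).
#' @export
aggregate_deaths <- function(records, grid, assignment = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("age", "sex", "year", "tpu_id")
  if (is.null(assignment)) need <- c(setdiff(need, "tpu_id"), "income_group")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))

  n <- nrow(records)
  a_idx <- .age_idx_of(records$age, grid)
  p_idx <- .period_idx_of(records$year, grid)
  if (is.null(assignment)) {
    inc <- as.character(records$income_group)
  } else {
    inc <- stratum_of(records$year, records$tpu_id, assignment)
  }
  sex <- as.character(records$sex)

  drop_age <- is.na(a_idx)
  drop_year <- !drop_age & is.na(p_idx)
  drop_sep <- !drop_age & !drop_year & is.na(inc)
  keep <- !(drop_age | drop_year | drop_sep)

  strata <- c("female.low", "female.high", "male.low", "male.high")
  deaths <- lapply(strata, function(s) matrix(0L, grid$n_age, grid$n_period))
  names(deaths) <- strata
  if (any(keep)) {
    key <- paste(sex[keep], inc[keep], sep = ".")
    bad <- !(key %in% strata)
    if (any(bad)) stop("unrecognized sex/income values: ",
                       paste(unique(key[bad]), collapse = ", "))
    cell <- (p_idx[keep] - 1L) * grid$n_age + a_idx[keep]
    for (s in strata) {
      sel <- key == s
      if (any(sel)) {
        tab <- tabulate(cell[sel], nbins = grid$n_age * grid$n_period)
        deaths[[s]] <- deaths[[s]] + matrix(tab, grid$n_age, grid$n_period)
      }
    }
  }
  dropped <- data.frame(
    reason = c("age_below_grid", "year_outside_periods", "unassigned_sep"),
    n = c(sum(drop_age), sum(drop_year), sum(drop_sep)))
  list(deaths = deaths, retained = sum(keep), dropped = dropped)
}

#' Keep only records whose ICD code is IHD
#'
#' @param records data.frame with `icd_code` and `icd_revision` columns.
#' @return The IHD subset, with attribute `invalid` giving the number of
#'   unparseable codes (also dropped, but reported).
#' @export
filter_ihd <- function(records) {
  flag <- is_ihd(records$icd_code, records$icd_revision)
  out <- records[!is.na(flag) & flag, , drop = FALSE]
  attr(out, "invalid") <- sum(is.na(flag))
  out
}

#' Aggregate annual population denominators into stratified person-years
#'
#' Annual mid-year population counts are summed over each period's calendar
#' years, giving person-years per cell (5 x mid-period population on the
#' default grid when all years are present).
#'
#' @param population data.frame with columns `age_group` (lower edge in
#'   years), `sex`, `year`, `tpu_id`, `population`.
#' @param grid A [lexis_grid()].
#' @param assignment A `sep_assignment` from [classify_tpus()], or `NULL` if
#'   an `income_group` column is present.
#' @return Named list of `n_age x n_period` person-years matrices per
#'   `"<sex>.<income>"` stratum.
#' @export
aggregate_population <- function(population, grid, assignment = NULL) {
  stopifnot(is.data.frame(population))
  a_idx <- .age_idx_of(population$age_group, grid)
  p_idx <- .period_idx_of(population$year, grid)
  if (is.null(assignment)) {
    inc <- as.character(population$income_group)
  } else {
    inc <- stratum_of(population$year, population$tpu_id, assignment)
  }
  keep <- !is.na(a_idx) & !is.na(p_idx) & !is.na(inc)
  strata <- c("female.low", "female.high", "male.low", "male.high")
  py <- lapply(strata, function(s) matrix(0, grid$n_age, grid$n_period))
  names(py) <- strata
  key <- paste(population$sex, inc, sep = ".")
  for (s in strata) {
    sel <- keep & key == s
    if (any(sel)) {
      m <- matrix(0, grid$n_age, grid$n_period)
      cell <- cbind(a_idx[sel], p_idx[sel])
      for (i in seq_len(sum(sel))) m[cell[i, 1], cell[i, 2]] <-
          m[cell[i, 1], cell[i, 2]] + population$population[which(sel)[i]]
      py[[s]] <- m
    }
  }
  py
}

#' Assemble stratum_counts objects from aggregated deaths and person-years
#'
#' @param agg Output of [aggregate_deaths()].
#' @param py Output of [aggregate_population()].
#' @param grid A [lexis_grid()].
#' @return Named list of [stratum_counts()] per stratum.
#' @export
build_stratum_counts <- function(agg, py, grid) {
  strata <- names(agg$deaths)
  out <- lapply(strata, function(s) {
    parts <- strsplit(s, ".", fixed = TRUE)[[1]]
    stratum_counts(grid, parts[1], parts[2], agg$deaths[[s]], py[[s]])
  })
  names(out) <- strata
  out
}
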
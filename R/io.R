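#' Read and write the package's delimited text formats
#'
#' All tabular artifacts are plain comma-separated text with a header row.
#' Every writer has a paired reader that reproduces the original object.
#'
#' @param records,path,grid,counts,tab,assignment,posterior,series,truth
#'   Objects/paths as per the individual functions.
#' @name apcmort_io
NULL

#' @describeIn apcmort_io Write death records
#'   (`age,sex,year,icd_revision,icd_code,tpu_id`).
#' @export
write_deaths <- function(records, path) {
  utils::write.csv(records[, c("age", "sex", "year", "icd_revision",
                               "icd_code", "tpu_id")], path, row.names = FALSE)
  invisible(path)
}

#' @describeIn apcmort_io Read death records.
#' @export
read_deaths <- function(path) {
  d <- utils::read.csv(path, colClasses = c(icd_code = "character",
                                            tpu_id = "character"))
  need <- c("age", "sex", "year", "icd_revision", "icd_code", "tpu_id")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("deaths file ", path, " missing columns: ",
                         paste(miss, collapse = ", "))
  d
}

#' @describeIn apcmort_io Write annual population denominators
#'   (`age_group,sex,year,tpu_id,population`).
#' @export
write_population <- function(records, path) {
  utils::write.csv(records[, c("age_group", "sex", "year", "tpu_id",
                               "population")], path, row.names = FALSE)
  invisible(path)
}

#' @describeIn apcmort_io Read annual population denominators.
#' @export
read_population <- function(path) {
  utils::read.csv(path, colClasses = c(tpu_id = "character"))
}

#' @describeIn apcmort_io Write a TPU income table
#'   (`tpu_id,census_year,median_income_per_capita`).
#' @export
write_tpu_income <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @describeIn apcmort_io Read a TPU income table.
#' @export
read_tpu_income <- function(path) {
  utils::read.csv(path, colClasses = c(tpu_id = "character"))
}

#' @describeIn apcmort_io Write a SEP assignment
#'   (`tpu_id,census_year,income_group,cutoff`).
#' @export
write_sep_assignment <- function(assignment, path) {
  utils::write.csv(as.data.frame(assignment), path, row.names = FALSE)
  invisible(path)
}

#' @describeIn apcmort_io Read a SEP assignment.
#' @export
read_sep_assignment <- function(path) {
  d <- utils::read.csv(path, colClasses = c(tpu_id = "character"))
  class(d) <- c("sep_assignment", "data.frame")
  d
}

.age_group_label <- function(grid) {
  lab <- paste0(grid$age_lower_edges, "-",
                grid$age_lower_edges + grid$age_width - 1L)
  if (grid$open_ended_top)
    lab[grid$n_age] <- paste0(grid$age_lower_edges[grid$n_age], "+")
  lab
}

#' @describeIn apcmort_io Write stratified grid counts in long format
#'   (`sex,income,age_group,period,deaths,person_years`, one row per cell).
#' @export
write_grid_counts <- function(counts, path) {
  if (inherits(counts, "stratum_counts")) counts <- list(counts)
  rows <- lapply(counts, function(cc) {
    g <- cc$grid
    data.frame(sex = cc$sex, income = cc$income_group,
               age_group = rep(.age_group_label(g), g$n_period),
               period = rep(.period_label(g$period_start_years, g$period_width),
                            each = g$n_age),
               deaths = as.integer(cc$deaths),
               person_years = as.numeric(cc$person_years))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @describeIn apcmort_io Read stratified grid counts back into a named list
#'   of [stratum_counts()].
#' @export
read_grid_counts <- function(path, grid) {
  d <- utils::read.csv(path)
  age_lab <- .age_group_label(grid)
  per_lab <- .period_label(grid$period_start_years, grid$period_width)
  if (!all(d$age_group %in% age_lab)) {
    bad <- which(!(d$age_group %in% age_lab))[1]
    stop("unknown age_group '", d$age_group[bad], "' at line ", bad + 1L,
         " of ", path)
  }
  if (!all(d$period %in% per_lab)) {
    bad <- which(!(d$period %in% per_lab))[1]
    stop("unknown period '", d$period[bad], "' at line ", bad + 1L, " of ", path)
  }
  out <- list()
  for (s in split(d, paste(d$sex, d$income, sep = "."))) {
    a <- match(s$age_group, age_lab)
    p <- match(s$period, per_lab)
    dm <- matrix(0L, grid$n_age, grid$n_period)
    pm <- matrix(0, grid$n_age, grid$n_period)
    dm[cbind(a, p)] <- s$deaths
    pm[cbind(a, p)] <- s$person_years
    out[[paste(s$sex[1], s$income[1], sep = ".")]] <-
      stratum_counts(grid, s$sex[1], s$income[1], dm, pm)
  }
  out
}

#' @describeIn apcmort_io Write retained posterior draws in long format
#'   (`chain,draw,parameter,value`).
#' @export
write_posterior <- function(posterior, path) {
  rows <- lapply(seq_along(posterior$draws), function(k) {
    m <- posterior$draws[[k]]
    data.frame(chain = k, draw = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @describeIn apcmort_io Rebuild an `apc_posterior` from a draws file
#'   (Rhat recomputed; the spec and config must be supplied).
#' @export
read_posterior <- function(path, spec, config) {
  d <- utils::read.csv(path)
  par_names <- .apc_par_names(spec$grid)
  chains <- lapply(sort(unique(d$chain)), function(k) {
    s <- d[d$chain == k, ]
    m <- matrix(NA_real_, max(s$draw), length(par_names),
                dimnames = list(NULL, par_names))
    m[cbind(s$draw, match(s$parameter, par_names))] <- s$value
    m
  })
  rh <- rhat(chains)
  structure(list(draws = chains, spec = spec, grid = spec$grid,
                 config = config, param_names = par_names, rhat = rh,
                 burn_in_used = NA_integer_,
                 converged = all(rh[!is.na(rh)] < config$rhat_threshold),
                 accept_rate = NULL),
            class = "apc_posterior")
}

#' @describeIn apcmort_io Write an ASR series with stratum columns
#'   (`sex,income,period_or_year,asr,asr_lo,asr_hi,observed_or_projected`).
#' @export
write_asr_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @describeIn apcmort_io Read an ASR series.
#' @export
read_asr_series <- function(path) utils::read.csv(path)

#' @describeIn apcmort_io Serialize a scenario truth (with its grid and
#'   person-years schedule) to YAML.
#' @export
write_truth <- function(truth, path) {
  obj <- list(sex = truth$sex, income_group = truth$income_group,
              mu = truth$mu, alpha = truth$alpha, beta = truth$beta,
              gamma = truth$gamma, sigma2 = as.list(truth$sigma2),
              anchors = truth$anchors,
              base_cohort_slope = truth$base_cohort_slope,
              person_years = apply(truth$person_years, 1, as.list),
              grid = list(age_start = truth$grid$age_lower_edges[1],
                          n_age = truth$grid$n_age,
                          age_width = truth$grid$age_width,
                          period_start = truth$grid$period_start_years[1],
                          n_period = truth$grid$n_period,
                          period_width = truth$grid$period_width,
                          open_ended_top = truth$grid$open_ended_top))
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @describeIn apcmort_io Read a scenario truth back from YAML.
#' @export
read_truth <- function(path) {
  o <- yaml::read_yaml(path)
  g <- do.call(lexis_grid, o$grid)
  py <- t(vapply(o$person_years, function(row) as.numeric(unlist(row)),
                 numeric(g$n_period)))
  structure(list(grid = g, sex = o$sex, income_group = o$income_group,
                 mu = o$mu, alpha = as.numeric(o$alpha),
                 beta = as.numeric(o$beta), gamma = as.numeric(o$gamma),
                 sigma2 = unlist(o$sigma2), person_years = py,
                 anchors = as.numeric(o$anchors),
                 base_cohort_slope = o$base_cohort_slope),
            class = "scenario_truth")
}
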
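#' Run configuration for the analysis pipeline
#'
#' A run is reproducible from the configuration, the input files and the
#' seed alone. The configuration is fully serializable to YAML
#' ([write_run_config()]).
#'
#' @param outdir Directory for all artifacts.
#' @param seed Master seed; every stage derives its own seed from it.
#' @param grid Named list of [lexis_grid()] arguments.
#' @param mcmc Named list of [mcmc_config()] arguments (without `seed`).
#' @param hyper Named list with `shape` and `rate` for the RW2 precision
#'   hyperprior.
#' @param n_ahead Projection horizon in periods.
#' @param joinpoint Named list with `max_k` and `min_obs`.
#' @param n_tpu Number of synthetic TPUs.
#' @param compare_models Whether `run_fit()` also tabulates DIC across the
#'   seven age/period/cohort submodels.
#' @param write_draws Whether `run_fit()` writes full draw files (they can be
#'   large) in addition to summaries.
#' @return A list of class `run_config`.
#' @export
run_config <- function(outdir = ".", seed = 1L,
                       grid = list(),
                       mcmc = list(n_chains = 5L, n_keep_total = 5000L,
                                   thin = 1L, burn_in = 2000L,
                                   max_burn_in = 20000L,
                                   rhat_threshold = 1.05),
                       hyper = list(shape = 0.001, rate = 0.001),
                       n_ahead = 3L,
                       joinpoint = list(max_k = 3L, min_obs = 2L),
                       n_tpu = 41L, compare_models = FALSE,
                       write_draws = TRUE) {
  structure(list(outdir = outdir, seed = as.integer(seed), grid = grid,
                 mcmc = mcmc, hyper = hyper, n_ahead = as.integer(n_ahead),
                 joinpoint = joinpoint, n_tpu = as.integer(n_tpu),
                 compare_models = isTRUE(compare_models),
                 write_draws = isTRUE(write_draws)),
            class = "run_config")
}

#' @describeIn run_config Serialize a configuration to YAML.
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @describeIn run_config Read a configuration back from YAML.
#' @export
read_run_config <- function(path) {
  o <- yaml::read_yaml(path)
  do.call(run_config, o)
}

.cfg_grid <- function(config) do.call(lexis_grid, config$grid)

.cfg_mcmc <- function(config, seed) {
  do.call(mcmc_config, c(config$mcmc, list(seed = as.integer(seed))))
}

.strata <- function() {
  list(female.low = c("female", "low"), female.high = c("female", "high"),
       male.low = c("male", "low"), male.high = c("male", "high"))
}

.log_line <- function(config, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " apcmort ",
                 as.character(utils::packageVersion("apcmort")),
                 " seed=", config$seed, " | ", ...)
  cat(line, "\n", file = file.path(config$outdir, "run.log"), append = TRUE)
  invisible(line)
}

#' Simulate a full synthetic study
#'
#' Generates the four sex x income scenario truths, expands them into
#' individual death records and annual population denominators over a shared
#' synthetic TPU income table, and writes all inputs plus the truth files and
#' the underlying grid counts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the truths, records, population, TPU table
#'   and grid counts.
#' @export
run_simulate <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  grid <- .cfg_grid(config)
  tpu <- make_tpu_income_table(n_tpu = config$n_tpu, seed = config$seed)
  truths <- list(); counts <- list(); recs <- list(); pops <- list()
  for (i in seq_along(.strata())) {
    s <- .strata()[[i]]
    truth <- default_scenario(s[1], s[2], grid)
    sim <- simulate_records(truth, tpu_table = tpu,
                            seed = config$seed + 10L * i)
    key <- names(.strata())[i]
    truths[[key]] <- truth
    counts[[key]] <- sim$counts
    recs[[key]] <- sim$records
    pops[[key]] <- sim$population
    write_truth(truth, file.path(config$outdir, paste0("truth_", key, ".yaml")))
  }
  records <- do.call(rbind, recs)
  population <- do.call(rbind, pops)
  write_deaths(records, file.path(config$outdir, "deaths.csv"))
  write_population(population, file.path(config$outdir, "population.csv"))
  write_tpu_income(tpu, file.path(config$outdir, "tpu_income.csv"))
  write_grid_counts(counts, file.path(config$outdir, "grid_counts.csv"))
  .log_line(config, "simulate: ", nrow(records), " records, ",
            length(counts), " strata")
  invisible(list(truths = truths, records = records, population = population,
                 tpu_table = tpu, counts = counts))
}

#' Classify TPUs from an income file
#'
#' @param config A [run_config()]; reads `tpu_income.csv` from `outdir` and
#'   writes `sep_assignment.csv`.
#' @return Invisibly, the `sep_assignment`.
#' @export
run_classify <- function(config) {
  tpu <- read_tpu_income(file.path(config$outdir, "tpu_income.csv"))
  assignment <- classify_tpus(tpu)
  write_sep_assignment(assignment, file.path(config$outdir, "sep_assignment.csv"))
  .log_line(config, "classify: ", nrow(assignment), " TPU-year assignments")
  invisible(assignment)
}

#' Aggregate death records and denominators onto the stratified grid
#'
#' Reads `deaths.csv`, `population.csv` and `tpu_income.csv` from the output
#' directory, filters to IHD, classifies strata and writes
#' `grid_counts.csv` plus a dropped-record tally.
#'
#' @param config A [run_config()].
#' @return Invisibly, the named list of [stratum_counts()].
#' @export
run_aggregate <- function(config) {
  grid <- .cfg_grid(config)
  deaths <- read_deaths(file.path(config$outdir, "deaths.csv"))
  population <- read_population(file.path(config$outdir, "population.csv"))
  tpu <- read_tpu_income(file.path(config$outdir, "tpu_income.csv"))
  assignment <- classify_tpus(tpu)
  ihd <- filter_ihd(deaths)
  agg <- aggregate_deaths(ihd, grid, assignment)
  py <- aggregate_population(population, grid, assignment)
  counts <- build_stratum_counts(agg, py, grid)
  write_grid_counts(counts, file.path(config$outdir, "grid_counts.csv"))
  utils::write.csv(agg$dropped, file.path(config$outdir, "dropped.csv"),
                   row.names = FALSE)
  .log_line(config, "aggregate: retained ", agg$retained, ", dropped ",
            sum(agg$dropped$n))
  invisible(counts)
}

#' Fit the Bayesian APC model per stratum
#'
#' Reads `grid_counts.csv`, fits the full age-period-cohort model to every
#' stratum, writes posterior summaries (and optionally full draws), an Rhat
#' report and, if configured, the DIC comparison across the seven submodels.
#' Stops with a convergence-failure error if any stratum fails the Rhat
#' criterion.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of `apc_posterior` objects.
#' @export
run_fit <- function(config) {
  grid <- .cfg_grid(config)
  counts <- read_grid_counts(file.path(config$outdir, "grid_counts.csv"), grid)
  posteriors <- list()
  dic_rows <- list()
  for (i in seq_along(counts)) {
    key <- names(counts)[i]
    spec <- apc_model_spec(grid, hyper_shape = config$hyper$shape,
                           hyper_rate = config$hyper$rate)
    cfg <- .cfg_mcmc(config, config$seed + 100L * i)
    post <- sample_posterior(counts[[key]], spec, cfg)
    posteriors[[key]] <- post
    summ <- posterior_summary(post)
    utils::write.csv(summ, file.path(config$outdir,
                                     paste0("posterior_summary_", key, ".csv")),
                     row.names = FALSE)
    if (config$write_draws)
      write_posterior(post, file.path(config$outdir,
                                      paste0("posterior_draws_", key, ".csv")))
    dd <- dic(post, counts[[key]])
    dic_rows[[key]] <- data.frame(stratum = key, model = "age-period-cohort",
                                  dbar = dd$dbar, pd = dd$pd, dic = dd$dic)
    if (config$compare_models) {
      cmp <- compare_models(counts[[key]], grid, .cfg_mcmc(config,
                              config$seed + 100L * i + 50L),
                            hyper_shape = config$hyper$shape,
                            hyper_rate = config$hyper$rate)
      utils::write.csv(cmp, file.path(config$outdir,
                                      paste0("dic_comparison_", key, ".csv")),
                       row.names = FALSE)
    }
    .log_line(config, "fit ", key, ": max Rhat ",
              signif(max(post$rhat, na.rm = TRUE), 4),
              ", DIC ", signif(dd$dic, 6))
  }
  utils::write.csv(do.call(rbind, dic_rows),
                   file.path(config$outdir, "dic.csv"), row.names = FALSE)
  failed <- names(posteriors)[!vapply(posteriors, `[[`, logical(1), "converged")]
  if (length(failed))
    stop("convergence failure (Rhat criterion unmet) for strata: ",
         paste(failed, collapse = ", "))
  invisible(posteriors)
}

#' Project age-standardized rates and effect relative risks
#'
#' @param config A [run_config()].
#' @param posteriors Named list of `apc_posterior` objects from [run_fit()];
#'   if `NULL`, draws files are re-read from the output directory.
#' @return Invisibly, a named list of `projection_result`s; writes
#'   `asr_series.csv` and `relative_risks.csv`.
#' @export
run_project <- function(config, posteriors = NULL) {
  grid <- .cfg_grid(config)
  if (is.null(posteriors)) posteriors <- .read_posteriors(config, grid)
  std <- restrict_weights(who_standard(), grid)
  out <- list(); series_rows <- list(); rr_rows <- list()
  for (i in seq_along(posteriors)) {
    key <- names(posteriors)[i]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    proj <- project_mortality(posteriors[[key]], n_ahead = config$n_ahead,
                              seed = config$seed + 1000L + i, std = std)
    out[[key]] <- proj
    s <- proj$asr_series
    series_rows[[key]] <- cbind(sex = parts[1], income = parts[2],
                                period_or_year = s$period, s[, -(1:3)])
    rr <- relative_risks(posteriors[[key]])
    rr_rows[[key]] <- rbind(
      cbind(sex = parts[1], income = parts[2], dimension = "period", rr$period),
      cbind(sex = parts[1], income = parts[2], dimension = "cohort", rr$cohort))
  }
  write_asr_series(do.call(rbind, series_rows),
                   file.path(config$outdir, "asr_series.csv"))
  utils::write.csv(do.call(rbind, rr_rows),
                   file.path(config$outdir, "relative_risks.csv"),
                   row.names = FALSE)
  .log_line(config, "project: ", config$n_ahead, " periods ahead for ",
            length(posteriors), " strata")
  invisible(out)
}

.read_posteriors <- function(config, grid) {
  files <- list.files(config$outdir, "^posterior_draws_.*\\.csv$",
                      full.names = TRUE)
  if (!length(files)) stop("no posterior draws found in ", config$outdir,
                           "; run run_fit() with write_draws = TRUE first")
  spec <- apc_model_spec(grid, hyper_shape = config$hyper$shape,
                         hyper_rate = config$hyper$rate)
  out <- lapply(files, read_posterior, spec = spec,
                config = .cfg_mcmc(config, config$seed))
  names(out) <- sub("^posterior_draws_(.*)\\.csv$", "\\1", basename(files))
  out
}

#' Joinpoint analysis of the estimated effect series
#'
#' Fits BIC-selected joinpoint models to the posterior-mean cohort and period
#' log relative risks of every stratum (observed window only) and writes a
#' summary table.
#'
#' @param config A [run_config()].
#' @param posteriors Named list of `apc_posterior`s, or `NULL` to re-read.
#' @return Invisibly, the joinpoint table data.frame (`joinpoints.csv`).
#' @export
run_joinpoint <- function(config, posteriors = NULL) {
  grid <- .cfg_grid(config)
  if (is.null(posteriors)) posteriors <- .read_posteriors(config, grid)
  rows <- list()
  for (key in names(posteriors)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    rr <- relative_risks(posteriors[[key]])
    for (dimn in c("cohort", "period")) {
      d <- rr[[dimn]]
      fit <- joinpoint(d$center_year, log(d$rr),
                       max_k = config$joinpoint$max_k,
                       min_obs = config$joinpoint$min_obs)
      rows[[paste(key, dimn)]] <- data.frame(
        sex = parts[1], income = parts[2], dimension = dimn,
        n_joinpoints = fit$n_joinpoints,
        positions = paste(fit$joinpoint_positions, collapse = ";"),
        slopes = paste(signif(fit$segment_slopes, 5), collapse = ";"),
        sse = fit$sse, bic = fit$bic)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  utils::write.csv(tab, file.path(config$outdir, "joinpoints.csv"),
                   row.names = FALSE)
  .log_line(config, "joinpoint: ", nrow(tab), " series analysed")
  invisible(tab)
}

#' Plain-text report of a completed run
#'
#' Re-reads the written artifacts (ASR series, DIC table, joinpoints) and
#' writes `report.txt`; regenerating the report from saved outputs is
#' idempotent.
#'
#' @param config A [run_config()].
#' @return Invisibly, the report lines.
#' @export
run_report <- function(config) {
  lines <- c("apcmort run report", paste0("seed: ", config$seed), "")
  asr_path <- file.path(config$outdir, "asr_series.csv")
  if (file.exists(asr_path)) {
    asr <- read_asr_series(asr_path)
    lines <- c(lines, "Age-standardized rates per 100,000 (30+, WHO standard):")
    for (key in unique(paste(asr$sex, asr$income))) {
      s <- asr[paste(asr$sex, asr$income) == key, ]
      first <- s[1, ]; last <- s[nrow(s), ]
      lines <- c(lines, sprintf("  %s: %s %.1f (%.1f-%.1f) -> %s %.1f (%.1f-%.1f) [%s]",
                                key, first$period_or_year, first$asr,
                                first$asr_lo, first$asr_hi,
                                last$period_or_year, last$asr, last$asr_lo,
                                last$asr_hi, last$observed_or_projected))
    }
  }
  dic_path <- file.path(config$outdir, "dic.csv")
  if (file.exists(dic_path)) {
    dd <- utils::read.csv(dic_path)
    lines <- c(lines, "", "DIC per stratum (full model):",
               sprintf("  %s: %.2f (pD %.2f)", dd$stratum, dd$dic, dd$pd))
  }
  jp_path <- file.path(config$outdir, "joinpoints.csv")
  if (file.exists(jp_path)) {
    jp <- utils::read.csv(jp_path)
    lines <- c(lines, "", "Joinpoints (BIC-selected):",
               sprintf("  %s %s %s: k=%d at [%s]", jp$sex, jp$income,
                       jp$dimension, jp$n_joinpoints,
                       ifelse(is.na(jp$positions), "", jp$positions)))
  }
  writeLines(lines, file.path(config$outdir, "report.txt"))
  .log_line(config, "report written")
  invisible(lines)
}
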
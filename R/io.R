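#' Trial-log and pipeline input/output
#'
#' Trial logs and covariate tables travel as plain comma-separated text
#' with a fixed header; `write_trials()` followed by `read_trials()` is
#' the identity, and re-writing a read file reproduces it byte for byte.
#'
#' @name io
NULL

.TRIAL_COLUMNS <- c("subject_id", "trial", "block", "staircase",
                    "effort_level", "reward", "decision", "success",
                    "clicks", "points")

#' Write a trial log
#'
#' @param trials trial data.frame with the canonical columns
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(.TRIAL_COLUMNS, names(trials))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  utils::write.csv(trials[, .TRIAL_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a trial log
#'
#' Malformed rows are reported with their line numbers; an empty file with
#' a valid header yields an empty dataset.
#'
#' @param path input file path
#' @return trial data.frame
#' @export
read_trials <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(header, .TRIAL_COLUMNS)) {
    stop("unexpected header in ", path, "; expected: ",
         paste(.TRIAL_COLUMNS, collapse = ","))
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(subject_id = "integer",
                                      trial = "integer", block = "integer",
                                      staircase = "integer",
                                      effort_level = "integer",
                                      reward = "integer",
                                      decision = "character",
                                      success = "logical",
                                      clicks = "integer",
                                      points = "integer"))
  bad <- which(!d$decision %in% c("accept", "reject"))
  if (length(bad)) {
    stop("invalid decision value on line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  }
  bad <- which(d$effort_level < 1 | d$effort_level > 4 |
                 d$reward < 2 | d$reward > 5)
  if (length(bad)) {
    stop("offer out of bounds on line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  }
  d
}

#' Write / read a covariate table
#'
#' @param covariates covariate data.frame
#' @param path file path
#' @return `path` / data.frame
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' @param n_subjects simulated cohort size
#' @param seed master seed for every pipeline stage
#' @param preset population preset (`"paper-like"` or `"null"`)
#' @param models model names fit and compared (the default fits the three
#'   full-parameter configurations; pass `model_registry()$name` for all
#'   nine)
#' @param mcmc an [mcmc_config()]
#' @param ppc_draws posterior draws used in the predictive check
#' @param out_dir output directory
#' @return list of class `"pipeline_config"`
#' @export
pipeline_config <- function(n_subjects = 60, seed = 1,
                            preset = "paper-like",
                            models = c("full_parabolic", "full_linear",
                                       "full_exponential"),
                            mcmc = mcmc_config(warmup = 1000,
                                               sampling = 2000,
                                               chains = 2, thin = 2,
                                               seed = seed),
                            ppc_draws = 500,
                            out_dir = tempfile("effortdm_run_")) {
  structure(as.list(environment()), class = "pipeline_config")
}

.write_table <- function(d, dir, name) {
  utils::write.csv(d, file.path(dir, name), row.names = FALSE, quote = FALSE)
}

#' Run the end-to-end pipeline
#'
#' Generates a synthetic population, simulates sessions, applies the
#' exclusion rules, fits the configured models hierarchically, compares
#' them by PSIS-LOO, runs the posterior predictive check on the
#' best-ranked model, and computes the model-agnostic acceptance analyses.
#' Every artifact is written as delimited text into the output directory
#' together with the verbatim effective configuration, so an identical
#' configuration and seed reproduce identical files.
#'
#' @param config a [pipeline_config()]
#' @return the output directory path, invisibly; the full result list is
#'   attached as attribute `"results"`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pop_cfg <- population_config(n_subjects = config$n_subjects,
                               preset = config$preset, seed = config$seed)
  pop <- generate_population(pop_cfg)
  trials <- simulate_cohort(pop$agents, seed = config$seed + 1L)

  write_trials(trials, file.path(config$out_dir, "trials.csv"))
  write_covariates(pop$covariates, file.path(config$out_dir, "covariates.csv"))
  .write_table(pop$truth, config$out_dir, "generative_truth.csv")
  .write_table(pop$calibration, config$out_dir, "calibration.csv")

  excl <- apply_exclusions(trials, pop$covariates, pop$calibration)
  .write_table(excl$rules, config$out_dir, "exclusions.csv")
  keep <- trials$subject_id %in% excl$survivors

  fits <- lapply(config$models, function(m) {
    fit_hierarchical(trials[keep, ], model = m, config = config$mcmc)
  })
  names(fits) <- config$models
  comparison <- loo_compare(fits)
  .write_table(as.data.frame(comparison), config$out_dir, "model_comparison.csv")

  best <- fits[[comparison$model[1]]]
  ppc <- posterior_predictive(best, trials[keep, ], ndraws = config$ppc_draws,
                              seed = config$seed + 2L)
  .write_table(data.frame(marginal = names(ppc$r2), r2 = as.numeric(ppc$r2)),
               config$out_dir, "ppc_r2.csv")
  .write_table(best$subject_params, config$out_dir, "subject_params.csv")
  .write_table(best$group_params, config$out_dir, "group_params.csv")

  am <- acceptance_matrix(trials[keep, ])
  .write_table(data.frame(effort = rep(1:4, 4), reward = rep(2:5, each = 4),
                          proportion = as.numeric(am$matrix)),
               config$out_dir, "acceptance_matrix.csv")
  ert <- effort_reward_test(trials[keep, ])
  .write_table(ert$anova, config$out_dir, "effort_reward_anova.csv")

  cfg_lines <- c(
    paste0("seed: ", config$seed),
    paste0("preset: ", config$preset),
    paste0("n_subjects: ", config$n_subjects),
    paste0("models: ", paste(config$models, collapse = ",")),
    paste0("mcmc: warmup=", config$mcmc$warmup, " sampling=",
           config$mcmc$sampling, " chains=", config$mcmc$chains,
           " thin=", config$mcmc$thin, " seed=", config$mcmc$seed),
    paste0("ppc_draws: ", config$ppc_draws),
    paste0("package_version: ", as.character(utils::packageVersion("effortdm")))
  )
  writeLines(cfg_lines, file.path(config$out_dir, "provenance.txt"))

  res <- list(population = pop, exclusions = excl, fits = fits,
              comparison = comparison, ppc = ppc, acceptance = am,
              effort_reward = ert)
  out <- config$out_dir
  attr(out, "results") <- res
  invisible(out)
}
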
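#' Run the full screening / intervention model
#'
#' Runs the decision tree and Markov microsimulation for each requested
#' strategy at each requested initiation age, with common random numbers
#' across strategies (the same master seed drives the baseline assignment
#' and the transition draws of every arm), and summarises outcomes against
#' the control arm.
#'
#' @param params `dm_parameters` (defaults to the baseline set).
#' @param life_table a `dm_life_table` (defaults to the bundled synthetic
#'   fixture).
#' @param ages initiation ages to run (subset of 25/40/60).
#' @param arms strategies to run; `"control"` is added automatically when a
#'   comparison is possible.
#' @param n cohort size per arm (default `params$settings$cohort_size`).
#' @param seed master integer seed.
#' @return an object of class `dm_run`: list with `summary` (a data.frame
#'   of per-arm, per-age aggregates, see [summarize_outcomes()]),
#'   `subjects` (nested list `[[age]][[arm]]` of per-subject outcome
#'   data.frames) and the run settings.
#' @export
#' @examples
#' run <- run_model(n = 2000, ages = 25, seed = 1)
#' run$summary[, c("strategy", "qalys", "cost", "saving_vs_control")]
run_model <- function(params = default_parameters(),
                      life_table = default_life_table(),
                      ages = INITIATION_AGES,
                      arms = STRATEGY_IDS,
                      n = params$settings$cohort_size,
                      seed = 1L) {
  arms <- match.arg(arms, STRATEGY_IDS, several.ok = TRUE)
  if (!"control" %in% arms) arms <- c(arms, "control")
  ages <- as.integer(ages)
  stopifnot(all(ages %in% INITIATION_AGES))
  validate_transitions(params, life_table)

  subjects <- list()
  summaries <- list()
  for (age in ages) {
    by_arm <- list()
    for (arm in arms) {
      dist <- initial_distribution(arm, params)
      cohort <- sample_cohort(dist, n, seed)
      sim <- run_microsim(cohort, arm, params, age, life_table, seed)
      by_arm[[arm]] <- subject_outcomes(sim, params)
    }
    subjects[[as.character(age)]] <- by_arm
    summaries[[as.character(age)]] <-
      summarize_outcomes(by_arm, params, age)
  }
  out <- list(summary = do.call(rbind, summaries),
              subjects = subjects,
              params = params, ages = ages, arms = arms,
              n = as.integer(n), seed = as.integer(seed))
  rownames(out$summary) <- NULL
  class(out) <- "dm_run"
  out
}

#' @export
print.dm_run <- function(x, ...) {
  cat(sprintf("<dm_run> n = %d per arm, seed = %d, ages: %s\n",
              x$n, x$seed, paste(x$ages, collapse = ", ")))
  cols <- c("strategy", "initiation_age", "remaining_years", "qalys",
            "cost", "saving_vs_control", "increment_qalys_vs_control",
            "extra_time_onset")
  print(format(x$summary[, cols], digits = 4), ...)
  invisible(x)
}

#' One-call reproducible test cohort
#'
#' Convenience fixture: builds the baseline assignment distribution for an
#' arm and samples a cohort from it.
#'
#' @param n cohort size.
#' @param arm strategy id.
#' @param params `dm_parameters`.
#' @param seed integer seed.
#' @return a cohort data.frame (see [sample_cohort()]).
#' @export
generate_test_cohort <- function(n, arm, params = default_parameters(),
                                 seed = 1L) {
  sample_cohort(initial_distribution(arm, params), n, seed)
}
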
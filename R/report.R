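## Report writers and command-style entry points.  CSV is the primary
## exchange format with a JSON mirror; money and years/QALYs are written to
## 2 decimal places and rates to 4.


## internal: content hash of the parameter set (and run settings) so a
## manifest identifies exactly what produced the outputs
params_hash <- function(params, extra = list()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(list(params = unclass(params), extra = extra), tmp,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Extra-time table (time gained before onset and complications)
#'
#' Per-strategy, per-age years gained by baseline-IGT subjects before
#' diabetes onset and before any complication, relative to control.
#'
#' @param run a `dm_run`.
#' @return wide data.frame, one row per non-control strategy.
#' @export
extra_time_table <- function(run) {
  s <- run$summary[run$summary$strategy != "control", ]
  ages <- sort(unique(s$initiation_age))
  out <- data.frame(strategy = unique(s$strategy))
  for (age in ages) {
    v <- s[s$initiation_age == age, ]
    i <- match(out$strategy, v$strategy)
    out[[paste0("onset_age", age)]] <- round_half_up(v$extra_time_onset[i], 2)
    out[[paste0("complication_age", age)]] <-
      round_half_up(v$extra_time_complication[i], 2)
  }
  out
}

#' Clinical and economic outcome table
#'
#' Per-strategy, per-age remaining life years, costs (with subject-level
#' interval), cost savings, QALYs (with interval) and QALY increments
#' versus control.
#'
#' @param run a `dm_run`.
#' @return long data.frame, one row per strategy x age.
#' @export
outcome_table <- function(run) {
  s <- run$summary
  data.frame(
    initiation_age = s$initiation_age,
    strategy = s$strategy,
    remaining_life_years = round_half_up(s$remaining_years, 1),
    costs = round_half_up(s$cost, 2),
    costs_lo = round_half_up(s$cost_lo, 2),
    costs_hi = round_half_up(s$cost_hi, 2),
    saving_costs = round_half_up(s$saving_vs_control, 2),
    qalys = round_half_up(s$qalys, 2),
    qalys_lo = round_half_up(s$qalys_lo, 2),
    qalys_hi = round_half_up(s$qalys_hi, 2),
    increment_qalys = round_half_up(s$increment_qalys_vs_control, 2))
}

#' Run the model and write report files
#'
#' Executes [run_model()] and writes `table_extra_time.csv` (time gained
#' before onset/complications), `table_outcomes.csv` (costs, savings,
#' QALYs, increments), `outcomes.json` (the full summary), a reproducibility
#' `manifest.json` (configuration hash, seed, sizes, timestamp) and,
#' optionally, a per-subject-cycle trajectory dump.
#'
#' @param config path to a YAML/JSON configuration file (optional).
#' @param overrides named nested list of parameter overrides applied over
#'   the configuration (see [load_parameters()]).
#' @param seed master seed.
#' @param ages initiation ages.
#' @param arms strategies.
#' @param n cohort size per arm (default from configuration).
#' @param out_dir output directory (created if missing).
#' @param life_table_file optional life-table file; default bundled fixture.
#' @param dump_trajectories write `trajectories.csv` (subject, cycle, age,
#'   state) for every arm -- large; off by default.
#' @param quiet suppress progress messages.
#' @return the `dm_run`, invisibly.
#' @export
cmd_run <- function(config = NULL, overrides = list(), seed = 1L,
                    ages = INITIATION_AGES,
                    arms = STRATEGY_IDS, n = NULL, out_dir = ".",
                    life_table_file = NULL, dump_trajectories = FALSE,
                    quiet = FALSE) {
  params <- load_parameters(config, overrides)
  if (is.null(n)) n <- params$settings$cohort_size
  life_table <- if (is.null(life_table_file)) default_life_table()
  else read_life_table(life_table_file)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  if (!quiet)
    message(sprintf("running %d arms x %d ages, n = %d, seed = %d",
                    length(arms), length(ages), n, seed))
  run <- run_model(params, life_table, ages, arms, n, seed)

  write.csv(extra_time_table(run),
            file.path(out_dir, "table_extra_time.csv"), row.names = FALSE)
  write.csv(outcome_table(run),
            file.path(out_dir, "table_outcomes.csv"), row.names = FALSE)
  jsonlite::write_json(run$summary, file.path(out_dir, "outcomes.json"),
                       dataframe = "rows", digits = NA, na = "null")
  manifest <- list(config = if (is.null(config)) "defaults" else config,
                   seed = as.integer(seed), n = as.integer(n),
                   ages = as.integer(ages), arms = arms,
                   parameter_hash = params_hash(params,
                                                list(seed = seed, n = n)),
                   created = format(Sys.time(), tz = "UTC",
                                    usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (dump_trajectories) dump_trajectory_csv(run, params, life_table,
                                             out_dir)
  invisible(run)
}

## internal: re-simulate and dump subject-cycle state sequences
dump_trajectory_csv <- function(run, params, life_table, out_dir) {
  rows <- list()
  for (age in run$ages) {
    for (arm in run$arms) {
      cohort <- generate_test_cohort(run$n, arm, params, run$seed)
      sim <- run_microsim(cohort, arm, params, age, life_table, run$seed)
      H <- ncol(sim$states) - 1L
      rows[[paste(age, arm)]] <- data.frame(
        strategy = arm, initiation_age = age,
        subject = rep(seq_len(nrow(sim$states)), times = H + 1L),
        cycle = rep(0:H, each = nrow(sim$states)),
        age = rep(age + 0:H, each = nrow(sim$states)),
        state = MARKOV_STATES[as.vector(sim$states)])
    }
  }
  write.csv(do.call(rbind, rows), file.path(out_dir, "trajectories.csv"),
            row.names = FALSE)
}

#' Run the sensitivity analysis and write its tables
#'
#' Executes [run_sensitivity()] over the default one-way grid and writes
#' the long-format results (`sensitivity_long.csv`), the compliance and
#' detection pivots of cost savings (`sensitivity_compliance.csv`,
#' `sensitivity_detection.csv`) and a manifest.
#'
#' @inheritParams cmd_run
#' @param grid scenario list; default [default_scenario_grid()].
#' @return the long-format sensitivity data.frame, invisibly.
#' @export
cmd_sensitivity <- function(config = NULL, overrides = list(), seed = 1L,
                            ages = INITIATION_AGES,
                            arms = c("diet", "exercise", "duo", "screen_only"),
                            n = NULL, out_dir = ".",
                            grid = default_scenario_grid(),
                            life_table_file = NULL, quiet = FALSE) {
  if (!length(grid)) stop("scenario grid is empty")
  params <- load_parameters(config, overrides)
  if (is.null(n)) n <- params$settings$cohort_size
  life_table <- if (is.null(life_table_file)) default_life_table()
  else read_life_table(life_table_file)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  if (!quiet)
    message(sprintf("running %d scenarios x %d arms x %d ages, n = %d",
                    length(grid) + 1L, length(arms), length(ages), n))
  sens <- run_sensitivity(grid, params, life_table, ages, arms, n, seed)
  write.csv(sens, file.path(out_dir, "sensitivity_long.csv"),
            row.names = FALSE)
  write.csv(pivot_savings(sens),
            file.path(out_dir, "sensitivity_compliance.csv"),
            row.names = FALSE)
  det <- pivot_savings(sens, c("IGT detection level 80%",
                               "IGT detection level 60%"))
  write.csv(det, file.path(out_dir, "sensitivity_detection.csv"),
            row.names = FALSE)
  manifest <- list(config = if (is.null(config)) "defaults" else config,
                   seed = as.integer(seed), n = as.integer(n),
                   ages = as.integer(ages), arms = arms,
                   scenarios = names(grid),
                   parameter_hash = params_hash(params,
                                                list(seed = seed, n = n)),
                   created = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(sens)
}
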
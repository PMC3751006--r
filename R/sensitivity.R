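## One-way sensitivity engine: a grid of single-parameter perturbations,
## each re-running the full model with the same master seed (common random
## numbers), so scenario deltas are not swamped by Monte-Carlo noise.

#' Construct a sensitivity scenario
#'
#' A scenario perturbs exactly one model assumption: either multiplying the
#' values at one or more parameter paths (a parameter "group", e.g. every
#' arm's complication incidence vector) by a common factor, or replacing
#' them with a fixed value.
#'
#' @param label human-readable scenario name.
#' @param paths character vector of dotted paths into the parameter list
#'   (e.g. `"shared.normal_to_igt"`, `"strategies.*.igt_to_dm"`; `*`
#'   expands over all names at that level).
#' @param multiplier multiplicative factor (exclusive with `value`).
#' @param value replacement value (exclusive with `multiplier`).
#' @return a `dm_scenario` list.
#' @export
sens_scenario <- function(label, paths, multiplier = NULL, value = NULL) {
  if (is.null(multiplier) == is.null(value))
    stop("exactly one of 'multiplier' or 'value' must be given")
  structure(list(label = label, paths = paths,
                 multiplier = multiplier, value = value),
            class = "dm_scenario")
}

## internal: expand a dotted path (with * wildcards) to index vectors
expand_paths <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  walk <- function(keys, parts) {
    if (!length(parts)) return(list(keys))
    node <- params
    for (k in keys) node <- node[[k]]
    p <- parts[[1]]
    nms <- if (identical(p, "*")) names(node) else p
    out <- list()
    for (nm in nms) {
      if (is.null(node[[nm]]))
        stop("unknown parameter path component '", nm, "' in '", path, "'")
      out <- c(out, walk(c(keys, nm), parts[-1]))
    }
    out
  }
  walk(character(), parts)
}

#' Apply a scenario to a parameter set
#'
#' Returns the perturbed parameters.  Probabilities and utilities pushed
#' outside \[0, 1\] by a multiplier are clamped with a warning (the result
#' is still returned so directional analyses can proceed).
#'
#' @param params `dm_parameters`.
#' @param scenario a [sens_scenario()].
#' @return perturbed, validated `dm_parameters`.
#' @export
apply_scenario <- function(params, scenario) {
  stopifnot(inherits(scenario, "dm_scenario"))
  p <- unclass(params)
  for (path in scenario$paths) {
    if (identical(path, "utilities.table")) {
      ## utility perturbations act on the disease states only; normal (1)
      ## and death (0) are anchors of the QALY scale
      ut <- p$utilities$table
      dis <- setdiff(rownames(ut), c("normal", "death"))
      ut[dis, ] <- if (!is.null(scenario$multiplier))
        ut[dis, ] * scenario$multiplier else scenario$value
      p$utilities$table <- ut
      next
    }
    for (keys in expand_paths(p, path)) {
      cur <- p[[keys]]
      p[[keys]] <- if (!is.null(scenario$multiplier))
        cur * scenario$multiplier else
          if (length(cur) > 1 && length(scenario$value) == 1)
            cur * 0 + scenario$value else scenario$value
    }
  }
  class(p) <- "dm_parameters"
  validate_parameters(p, clamp = TRUE)
}

#' Default one-way sensitivity grid
#'
#' The grid of single-parameter perturbations analysed by the model:
#' +/-20% on the screening positive rates, IGT-to-diabetes incidence,
#' complication incidence and mortality, every cost group, the utilities
#' and the discount rate; x3.0 / x0.5 on the normal-to-IGT incidence
#' (the prevalence contrast between young and old adults is about 200%);
#' and reduced IGT detection (80%, 60%) and screening compliance
#' (80%, 60%).
#'
#' @return named list of `dm_scenario` objects.
#' @export
default_scenario_grid <- function() {
  g <- list()
  add <- function(label, paths, multiplier = NULL, value = NULL)
    g[[label]] <<- sens_scenario(label, paths, multiplier, value)
  both <- function(stub, paths) {
    add(paste0(stub, " x0.8"), paths, multiplier = 0.8)
    add(paste0(stub, " x1.2"), paths, multiplier = 1.2)
  }
  ## screening performance: the 2h-PG positive fraction is 1 - neg_rate, so
  ## a +/-20% change of the positive fraction is applied as a replacement
  add("2hPG positive rate x0.8", "screening.neg_rate_2hpg", value = 1 - 0.8 * 0.04)
  add("2hPG positive rate x1.2", "screening.neg_rate_2hpg", value = 1 - 1.2 * 0.04)
  both("OGTT positive rate", "screening.ogtt_positive_rate")
  both("diagnosed IGT proportion", "screening.igt_fraction_of_positive")
  both("IGT to diabetes incidence", "strategies.*.igt_to_dm")
  both("complication incidence", "strategies.*.complication_incidence")
  both("complication mortality", "strategies.*.complication_mortality")
  both("screening cost", "costs.screening")
  both("intervention cost", "strategies.*.annual_intervention_cost")
  both("treatment costs", c("costs.onset_dm", "costs.cvd", "costs.nephropathy",
                            "costs.neuropathy", "costs.retinopathy"))
  both("utilities", "utilities.table")
  both("discount rate", "settings.discount_rate")
  add("normal to IGT incidence x3.0", "shared.normal_to_igt", multiplier = 3.0)
  add("normal to IGT incidence x0.5", "shared.normal_to_igt", multiplier = 0.5)
  add("IGT detection level 80%", "screening.detection_level", value = 0.8)
  add("IGT detection level 60%", "screening.detection_level", value = 0.6)
  add("screening compliance 80%", "screening.compliance", value = 0.8)
  add("screening compliance 60%", "screening.compliance", value = 0.6)
  g
}

#' Run a one-way sensitivity analysis
#'
#' Re-runs the full model under each scenario with the same master seed as
#' the baseline (common random numbers) and tabulates cost savings and QALY
#' increments versus each scenario's own control arm, in long format.
#'
#' @param grid list of scenarios (default [default_scenario_grid()]); a
#'   `baseline` row (no perturbation) is always included first.
#' @param params `dm_parameters`.
#' @param life_table a `dm_life_table`.
#' @param ages initiation ages.
#' @param arms strategies (control is always added).
#' @param n cohort size per arm.
#' @param seed master seed shared by all scenarios.
#' @return data.frame with columns `scenario`, `strategy`,
#'   `initiation_age`, `saving_vs_control`, `increment_qalys_vs_control`,
#'   `clamped` (whether the scenario pushed a probability/utility out of
#'   range).
#' @export
run_sensitivity <- function(grid = default_scenario_grid(),
                            params = default_parameters(),
                            life_table = default_life_table(),
                            ages = INITIATION_AGES,
                            arms = c("diet", "exercise", "duo", "screen_only"),
                            n = params$settings$cohort_size,
                            seed = 1L) {
  if (!length(grid)) stop("scenario grid is empty")
  scenarios <- c(list(baseline = NULL), grid)
  rows <- lapply(names(scenarios), function(snm) {
    sc <- scenarios[[snm]]
    clamped <- FALSE
    p <- if (is.null(sc)) params else
      withCallingHandlers(apply_scenario(params, sc),
                          warning = function(w) {
                            clamped <<- TRUE
                            invokeRestart("muffleWarning")
                          })
    run <- run_model(p, life_table, ages, arms, n, seed)
    s <- run$summary[run$summary$strategy != "control",
                     c("strategy", "initiation_age", "saving_vs_control",
                       "increment_qalys_vs_control")]
    cbind(scenario = snm, s, clamped = clamped)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compliance / detection pivot of savings
#'
#' Reshapes sensitivity results into the strategy x age table of cost
#' savings at baseline and reduced screening compliance (or detection)
#' levels.
#'
#' @param sens long-format result of [run_sensitivity()].
#' @param scenarios scenario labels to pivot, in column order after the
#'   baseline.
#' @return data.frame: one row per strategy, one column per age x scenario.
#' @export
pivot_savings <- function(sens,
                          scenarios = c("screening compliance 80%",
                                        "screening compliance 60%")) {
  keep <- c("baseline", scenarios)
  s <- sens[sens$scenario %in% keep, ]
  ages <- sort(unique(s$initiation_age))
  arms <- unique(s$strategy)
  out <- data.frame(strategy = arms)
  for (age in ages) {
    for (sc in keep) {
      col <- paste0("age", age, "_", gsub("[^0-9a-z]+", "_", tolower(sc)))
      v <- s[s$initiation_age == age & s$scenario == sc, ]
      out[[col]] <- v$saving_vs_control[match(arms, v$strategy)]
    }
  }
  out
}
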
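## Outcomes module: discounting, half-cycle correction, per-subject accrual
## of costs / QALYs / survival years, and per-arm summaries.

#' Discount factor
#'
#' `(1 + rate)^(-t)` for cycle index `t`; costs and QALYs are discounted at
#' 3% per year by default.
#'
#' @param t cycle index (years from initiation), >= 0.
#' @param rate annual discount rate.
#' @return discount factor(s).
#' @export
discount_factor <- function(t, rate = 0.03) {
  stopifnot(all(t >= 0))
  (1 + rate)^(-t)
}

#' Half-cycle correction weight
#'
#' Trapezoidal weighting of per-cycle accruals: weight 0.5 at cycle 0 and
#' at the horizon, 1 in between, so state membership is valued as occurring
#' mid-cycle.  Applied multiplicatively with the discount factor.
#'
#' @param t cycle index, `0 <= t <= horizon`.
#' @param horizon number of cycles.
#' @return weight(s) in `{0.5, 1}`.
#' @export
half_cycle_weight <- function(t, horizon) {
  stopifnot(all(t >= 0), all(t <= horizon))
  ifelse(t == 0 | t == horizon, 0.5, 1)
}

## internal: combined per-cycle weights for a horizon
cycle_weights <- function(horizon, rate) {
  t <- 0:horizon
  list(w = half_cycle_weight(t, horizon),
       d = discount_factor(t, rate))
}

#' Accrue costs, QALYs and survival years over trajectories
#'
#' Vectorised accrual over a state matrix.  Per cycle `t` (half-cycle
#' weighted and, for costs and QALYs, discounted):
#' * cost: the occupied state's annual treatment cost (onset of diabetes
#'   897, CVD 2078, nephropathy 1089, neuropathy 1324, retinopathy 888
#'   US$/year by default), plus the lifestyle-intervention annual cost at
#'   cycles 1..tunnel_length for intervened subjects still in a tunnel
#'   state at the previous cycle, plus the one-off screening cost charged
#'   in full at cycle 0;
#' * QALYs: the utility of the occupied state for the model's initiation
#'   age;
#' * survival years: undiscounted half-cycle-weighted years alive.
#'
#' @param states integer state matrix, `n x (horizon+1)` (cycle 0 first).
#' @param params `dm_parameters`.
#' @param initiation_age 25, 40 or 60 (selects the utility column).
#' @param treated logical vector: receives the lifestyle intervention.
#' @param screening_cost numeric vector of per-subject baseline screening
#'   costs.
#' @param intervention_cost annual intervention cost (US$/year) for treated
#'   subjects.
#' @return data.frame with per-subject `cost`, `qalys`, `survival_years`.
#' @export
accrue_trajectories <- function(states, params, initiation_age,
                                treated = rep(FALSE, nrow(states)),
                                screening_cost = rep(0, nrow(states)),
                                intervention_cost = 0) {
  n <- nrow(states)
  H <- ncol(states) - 1L
  se <- params$settings
  cw <- cycle_weights(H, se$discount_rate)
  wd <- cw$w * cw$d

  age_key <- as.character(initiation_age)
  ut <- params$utilities$table[, age_key]
  util_by_state <- c(ut[["normal"]], rep(ut[["igt"]], 7),
                     ut[["onset_dm"]], ut[["cvd"]], ut[["retinopathy"]],
                     ut[["nephropathy"]], ut[["neuropathy"]], ut[["death"]])
  cost_by_state <- c(0, rep(0, 7), params$costs$onset_dm, params$costs$cvd,
                     params$costs$retinopathy, params$costs$nephropathy,
                     params$costs$neuropathy, 0)

  Umat <- matrix(util_by_state[states], n)
  Cmat <- matrix(cost_by_state[states], n)
  qalys <- as.numeric(Umat %*% wd)
  cost <- as.numeric(Cmat %*% wd) + screening_cost

  tl <- min(se$tunnel_length, H)
  if (any(treated) && intervention_cost > 0 && tl >= 1) {
    ## annual intervention cost valued at the end of each tunnel year:
    ## charged at cycle t (t = 1..tunnel_length) when the subject occupied
    ## a tunnel state at cycle t-1
    in_tunnel <- matrix(states[, seq_len(tl), drop = FALSE] %in% TUNNEL_STATES, n)
    cost <- cost + treated * intervention_cost *
      as.numeric(in_tunnel %*% wd[1L + seq_len(tl)])
  }
  alive <- matrix(states != DEATH_STATE, n)
  survival <- as.numeric(alive %*% cw$w)
  data.frame(cost = cost, qalys = qalys, survival_years = survival)
}

#' Per-subject outcomes for a simulated arm
#'
#' Combines [accrue_trajectories()] with the event times and baseline flags
#' of a microsimulation result.
#'
#' @param sim a `dm_microsim` from [run_microsim()].
#' @param params `dm_parameters`.
#' @return data.frame, one row per subject: accruals, baseline state flags,
#'   `eligible` (member of the diabetes/IGT subgroup under
#'   `settings$eligibility`), and censored event times
#'   `time_to_dm_censored` / `time_to_complication_censored` -- the years
#'   spent free of the event, cut at death and at the horizon, so that
#'   between-arm differences measure event-free years gained.
#' @export
subject_outcomes <- function(sim, params) {
  co <- sim$cohort
  arm <- params$strategies[[sim$strategy]]
  acc <- accrue_trajectories(sim$states, params, sim$initiation_age,
                             treated = co$receives_intervention,
                             screening_cost = co$screening_cost,
                             intervention_cost = arm$annual_intervention_cost)
  H <- params$settings$horizon
  baseline_igt <- co$state == "igt"
  baseline_dm <- co$state == "onset_dm"
  incident_dm <- !baseline_dm & !is.na(sim$time_to_dm)
  eligible <- if (identical(params$settings$eligibility, "baseline_only"))
    baseline_igt | baseline_dm
  else baseline_igt | baseline_dm | incident_dm
  cbind(acc,
        data.frame(
          subject = co$subject,
          treated = co$receives_intervention,
          baseline_igt = baseline_igt,
          baseline_dm = baseline_dm,
          incident_dm = incident_dm,
          eligible = eligible,
          time_to_dm_censored = pmin(ifelse(is.na(sim$time_to_dm), H,
                                            sim$time_to_dm),
                                     ifelse(is.na(sim$death_cycle), H,
                                            sim$death_cycle), H),
          time_to_complication_censored =
            pmin(ifelse(is.na(sim$time_to_complication), H,
                        sim$time_to_complication),
                 ifelse(is.na(sim$death_cycle), H, sim$death_cycle), H),
          death_cycle = sim$death_cycle))
}

## internal: interval summary of subject-level values
value_range <- function(x, type) {
  if (!length(x)) return(c(NA_real_, NA_real_))
  if (identical(type, "minmax")) range(x)
  else unname(quantile(x, c(0.025, 0.975), names = FALSE))
}

#' Summarise per-strategy outcomes against control
#'
#' Produces the per-strategy, per-initiation-age outcome aggregates:
#' * remaining survival years and discounted QALYs, averaged over the
#'   diabetes/IGT subgroup (subjects with baseline IGT, baseline diabetes
#'   or -- under the default eligibility -- incident diabetes within the
#'   horizon), with subject-level 2.5-97.5 percentile intervals;
#' * discounted societal cost per subject, averaged both over all simulated
#'   subjects (`cost_all`) and over the subgroup (`cost_subgroup`), with
#'   the configured population (`settings$cost_population`) reported as
#'   `cost`;
#' * cost saving and QALY increment versus the control arm;
#' * extra time before diabetes onset and before any complication among
#'   baseline-IGT subjects, versus control: undiscounted event-free years
#'   (cut at death and at the horizon), so the difference is the mean
#'   event-free time gained.
#'
#' @param outcomes_by_arm named list of [subject_outcomes()] data.frames for
#'   one initiation age; must include `"control"`.
#' @param params `dm_parameters`.
#' @param initiation_age the age the arms were run at.
#' @return data.frame with one row per strategy.
#' @export
summarize_outcomes <- function(outcomes_by_arm, params, initiation_age) {
  if (!"control" %in% names(outcomes_by_arm))
    stop("the control arm must be present")
  rt <- params$settings$range_type
  pop <- params$settings$cost_population
  ctl <- outcomes_by_arm$control
  arm_stats <- function(df) {
    el <- df[df$eligible, , drop = FALSE]
    if (!nrow(el))
      warning("empty diabetes/IGT subgroup; subgroup outcomes are NA",
              call. = FALSE)
    bigt <- df[df$baseline_igt, , drop = FALSE]
    c(list(
      n = nrow(df), n_eligible = nrow(el),
      remaining_years = mean(el$survival_years),
      remaining_years_lo = value_range(el$survival_years, rt)[1],
      remaining_years_hi = value_range(el$survival_years, rt)[2],
      qalys = mean(el$qalys),
      qalys_lo = value_range(el$qalys, rt)[1],
      qalys_hi = value_range(el$qalys, rt)[2],
      cost_all = mean(df$cost),
      cost_subgroup = mean(el$cost),
      cost_lo = value_range(if (pop == "all") df$cost else el$cost, rt)[1],
      cost_hi = value_range(if (pop == "all") df$cost else el$cost, rt)[2],
      time_onset = mean(bigt$time_to_dm_censored),
      time_complication = mean(bigt$time_to_complication_censored)))
  }
  cs <- arm_stats(ctl)
  rows <- lapply(names(outcomes_by_arm), function(arm) {
    s <- arm_stats(outcomes_by_arm[[arm]])
    cost <- if (pop == "all") s$cost_all else s$cost_subgroup
    cost_ctl <- if (pop == "all") cs$cost_all else cs$cost_subgroup
    data.frame(
      strategy = arm, initiation_age = initiation_age,
      n = s$n, n_eligible = s$n_eligible,
      remaining_years = s$remaining_years,
      remaining_years_lo = s$remaining_years_lo,
      remaining_years_hi = s$remaining_years_hi,
      qalys = s$qalys, qalys_lo = s$qalys_lo, qalys_hi = s$qalys_hi,
      cost = cost, cost_lo = s$cost_lo, cost_hi = s$cost_hi,
      cost_all = s$cost_all, cost_subgroup = s$cost_subgroup,
      saving_vs_control = if (arm == "control") NA_real_ else cost_ctl - cost,
      increment_qalys_vs_control = if (arm == "control") NA_real_ else
        s$qalys - cs$qalys,
      extra_time_onset = if (arm == "control") NA_real_ else
        s$time_onset - cs$time_onset,
      extra_time_complication = if (arm == "control") NA_real_ else
        s$time_complication - cs$time_complication)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
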
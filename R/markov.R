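## Markov engine: annual-cycle individual-level simulation over the eight
## health states, with the IGT state expanded into six tunnel states (the
## six intervention years) plus a post-tunnel IGT state, and life-table
## competing mortality.
##
## Fixed state ordering (also the inverse-CDF ordering used by step()):
##   1 normal, 2..7 igt_t1..igt_t6, 8 igt_post, 9 onset_dm,
##   10 cvd, 11 retinopathy, 12 nephropathy, 13 neuropathy, 14 death

MARKOV_STATES <- c("normal", paste0("igt_t", 1:6), "igt_post", "onset_dm",
                   "cvd", "retinopathy", "nephropathy", "neuropathy", "death")
N_STATES <- length(MARKOV_STATES)
TUNNEL_STATES <- 2:7
IGT_STATES <- 2:8
COMPLICATION_STATES <- 10:13
DM_STATE <- 9L
DEATH_STATE <- 14L

#' Markov state names
#'
#' The fixed state ordering used throughout the engine: normal glucose
#' tolerance, the six IGT tunnel states, post-tunnel IGT, onset of diabetes,
#' the four complication states (CVD, retinopathy, nephropathy, neuropathy)
#' and absorbing death.
#'
#' @return character vector of the 14 state labels.
#' @export
markov_states <- function() MARKOV_STATES

## internal: full 14x14 annual transition matrix.
## Event ordering within a cycle: all-cause (life-table) death first with
## probability qx; conditional on survival, the state-specific transitions
## apply.  CVD- and nephropathy-specific mortality are added on top of qx;
## retinopathy and neuropathy carry background mortality only.
transition_matrix <- function(igt_dm_tunnel, igt_dm_post, comp_inc, comp_mort,
                              shared, qx) {
  M <- matrix(0, N_STATES, N_STATES,
              dimnames = list(MARKOV_STATES, MARKOV_STATES))
  s <- 1 - qx
  ## normal
  M[1, 2] <- s * shared$normal_to_igt
  M[1, 14] <- qx
  M[1, 1] <- s * (1 - shared$normal_to_igt)
  ## IGT tunnel states: progress to diabetes, revert to normal, or advance
  ## one tunnel year (after tunnel 6 survivors move to post-tunnel IGT)
  for (k in TUNNEL_STATES) {
    stay <- 1 - igt_dm_tunnel - shared$igt_to_normal
    if (stay < 0)
      stop("negative residual stay-probability in state ", MARKOV_STATES[k])
    M[k, DM_STATE] <- s * igt_dm_tunnel
    M[k, 1] <- s * shared$igt_to_normal
    M[k, if (k < 7) k + 1L else 8L] <- s * stay
    M[k, 14] <- qx
  }
  ## post-tunnel IGT
  stay <- 1 - igt_dm_post - shared$igt_to_normal
  if (stay < 0) stop("negative residual stay-probability in state igt_post")
  M[8, DM_STATE] <- s * igt_dm_post
  M[8, 1] <- s * shared$igt_to_normal
  M[8, 8] <- s * stay
  M[8, 14] <- qx
  ## onset of diabetes -> complications
  ci <- comp_inc[c("cvd", "retinopathy", "nephropathy", "neuropathy")]
  stay <- 1 - sum(ci)
  if (stay < 0) stop("negative residual stay-probability in state onset_dm")
  M[9, 10] <- s * ci[["cvd"]]
  M[9, 11] <- s * ci[["retinopathy"]]
  M[9, 12] <- s * ci[["nephropathy"]]
  M[9, 13] <- s * ci[["neuropathy"]]
  M[9, 9] <- s * stay
  M[9, 14] <- qx
  ## complications: CVD and nephropathy add disease-specific mortality
  M[10, 14] <- qx + s * comp_mort[["cvd"]]
  M[10, 10] <- 1 - M[10, 14]
  M[11, 14] <- qx; M[11, 11] <- s
  M[12, 14] <- qx + s * comp_mort[["nephropathy"]]
  M[12, 12] <- 1 - M[12, 14]
  M[13, 14] <- qx; M[13, 13] <- s
  M[14, 14] <- 1
  bad <- abs(rowSums(M) - 1) > 1e-12
  if (any(bad))
    stop("transition rows do not sum to 1: ",
         paste(MARKOV_STATES[bad], collapse = ", "))
  M
}

## internal: resolve the IGT->DM rates and complication rates that apply to
## a subject group in a given arm at a given cycle.
##   treated  : receives_intervention subjects (diet/exercise/duo)
##   column   : diagnosed subjects given the arm's printed column rates
##              (screen-alone arm when screen_alone_uses_column_rates=TRUE)
##   others   : control rates
group_rates <- function(strategy, params, age_key, cycle, group) {
  ctl <- params$strategies$control
  tl <- params$settings$tunnel_length
  if (group == "treated") {
    in_tunnel_years <- cycle <= tl
    r_int <- strategy$igt_to_dm[[age_key]]
    r_post <- if (identical(params$settings$post_tunnel_rate,
                            "last_intervention"))
      r_int else ctl$igt_to_dm[[age_key]]
    list(tunnel = if (in_tunnel_years) r_int else r_post,
         post = r_post,
         ci = strategy$complication_incidence,
         cm = strategy$complication_mortality)
  } else if (group == "column") {
    r <- strategy$igt_to_dm[[age_key]]
    list(tunnel = r, post = r,
         ci = strategy$complication_incidence,
         cm = strategy$complication_mortality)
  } else {
    r <- ctl$igt_to_dm[[age_key]]
    list(tunnel = r, post = r,
         ci = ctl$complication_incidence,
         cm = ctl$complication_mortality)
  }
}

#' One row of the annual transition matrix
#'
#' Composition per cycle: life-table all-cause death is applied first with
#' probability `qx`; conditional on survival the state-specific transitions
#' apply -- normal to IGT at the shared incidence; IGT to diabetes at the
#' arm/age rate (the intervention rate while in the six-year intervention,
#' the control rate otherwise) or back to normal; onset of diabetes to each
#' complication; CVD and nephropathy add their disease-specific mortality
#' on top of `qx` (retinopathy and neuropathy have background mortality
#' only); death is absorbing.
#'
#' @param state state label (see [markov_states()]).
#' @param strategy strategy list or id string.
#' @param params `dm_parameters`.
#' @param initiation_age 25, 40 or 60 (selects the age-specific rates).
#' @param qx annual all-cause death probability at the subject's current age.
#' @param in_intervention logical; subject is receiving the lifestyle
#'   intervention this cycle.
#' @return named numeric vector of transition probabilities over the 14
#'   states, summing to 1.
#' @export
#' @examples
#' p <- default_parameters()
#' r <- build_transition_row("onset_dm", "control", p, 40, qx = 0)
#' r[["onset_dm"]]  # 0.9184
build_transition_row <- function(state, strategy, params, initiation_age,
                                 qx, in_intervention = FALSE) {
  if (is.character(strategy))
    strategy <- params$strategies[[match.arg(strategy, names(params$strategies))]]
  check_probability(qx, "qx")
  age_key <- as.character(initiation_age)
  g <- group_rates(strategy, params, age_key,
                   cycle = if (in_intervention) 1L else
                     params$settings$tunnel_length + 1L,
                   group = if (in_intervention) "treated" else
                     if (identical(strategy$id, "control")) "others" else
                       if (isTRUE(params$settings$screen_alone_uses_column_rates) &&
                           identical(strategy$id, "screen_only")) "column"
                       else "others")
  M <- transition_matrix(g$tunnel, g$post, g$ci, g$cm, params$shared, qx)
  M[state, ]
}

#' Sample the next state
#'
#' Inverse-CDF draw over the fixed state ordering: the next state is the
#' first state whose cumulative probability exceeds the uniform draw.
#' Tunnel membership advances on stay (encoded in the matrix row), and
#' survivors of tunnel year six move to the post-tunnel IGT state.
#'
#' @param row named transition-probability vector (one matrix row).
#' @param u uniform draw in \[0, 1).
#' @return the next state label.
#' @export
step <- function(row, u) {
  idx <- 1L + sum(cumsum(row) <= u)   # smallest j with u < cum[j]
  MARKOV_STATES[min(idx, N_STATES)]
}

#' Run the individual-level Markov microsimulation for one arm
#'
#' Simulates every subject of a baseline cohort over the model horizon with
#' annual cycles.  Subjects flagged `receives_intervention` use the arm's
#' IGT-to-diabetes rate while in the tunnel during intervention years (the
#' first `tunnel_length` cycles) and the arm's complication rates
#' thereafter; all other subjects follow control-arm dynamics, so strategy
#' arms differ from control only through the screened-and-intervened
#' subjects (and the screening cost).  Each cycle consumes two uniform
#' draws per subject from matrices seeded with `seed + 1`: one against the
#' life-table background death probability (shared by every arm, so
#' background death times are identical across strategies) and one against
#' the survival-conditional transition row.  This two-stage composition is
#' the model's event ordering -- all-cause death first, disease transitions
#' conditional on survival -- and maximises the common-random-number
#' coupling between arms.
#'
#' @param cohort data.frame from [sample_cohort()].
#' @param strategy strategy list or id string.
#' @param params `dm_parameters`.
#' @param initiation_age 25, 40 or 60.
#' @param life_table a `dm_life_table` covering
#'   `initiation_age .. initiation_age + horizon - 1`.
#' @param seed master integer seed (the same one used for the cohort).
#' @return an object of class `dm_microsim`: list with the `n x (horizon+1)`
#'   integer state matrix `states` (cycle 0 in column 1), the cohort,
#'   strategy id, initiation age, and per-subject event times
#'   `time_to_dm` / `time_to_complication` / `death_cycle` (NA if the event
#'   does not occur within the horizon).
#' @export
run_microsim <- function(cohort, strategy, params, initiation_age,
                         life_table = default_life_table(), seed = 1L) {
  if (is.character(strategy))
    strategy <- params$strategies[[match.arg(strategy, names(params$strategies))]]
  n <- nrow(cohort)
  if (n < 1) stop("cohort must be nonempty")
  H <- params$settings$horizon
  age_key <- as.character(initiation_age)
  qx <- qx_lookup(life_table, initiation_age + seq_len(H) - 1L)

  S <- matrix(NA_integer_, n, H + 1L)
  S[, 1] <- c(normal = 1L, igt = 2L, onset_dm = DM_STATE)[cohort$state]

  treated <- cohort$receives_intervention
  column <- if (isTRUE(params$settings$screen_alone_uses_column_rates) &&
                identical(strategy$id, "screen_only"))
    cohort$diagnosed & cohort$state == "igt" else rep(FALSE, n)
  groups <- list(treated = which(treated),
                 column = which(column & !treated),
                 others = which(!treated & !column))

  set.seed(as.integer(seed) + 1L)
  U_death <- matrix(runif(n * H), n, H)
  U_trans <- matrix(runif(n * H), n, H)

  for (t in seq_len(H)) {
    s_now <- S[, t]
    s_new <- s_now
    for (gname in names(groups)) {
      idx <- groups[[gname]]
      if (!length(idx)) next
      g <- group_rates(strategy, params, age_key, cycle = t, group = gname)
      ## survival-conditional transition matrix (background death removed)
      M <- transition_matrix(g$tunnel, g$post, g$ci, g$cm,
                             params$shared, qx = 0)
      Cm <- t(apply(M, 1, cumsum))
      Cm[, N_STATES] <- 1              # guard float residue at the tail
      s_new[idx] <- 1L + rowSums(U_trans[idx, t] >= Cm[s_now[idx], , drop = FALSE])
    }
    ## background all-cause death applied first: overrides any transition
    dies <- s_now != DEATH_STATE & U_death[, t] < qx[t]
    s_new[dies] <- DEATH_STATE
    S[, t + 1L] <- s_new
  }

  first_time <- function(hit) {
    any_hit <- rowSums(hit) > 0
    ft <- max.col(hit, ties.method = "first") - 1L
    ft[!any_hit] <- NA_integer_
    ft
  }
  out <- list(states = S,
              cohort = cohort,
              strategy = strategy$id,
              initiation_age = initiation_age,
              seed = as.integer(seed),
              time_to_dm = first_time(matrix(S == DM_STATE, n)),
              time_to_complication = first_time(
                matrix(S %in% COMPLICATION_STATES, n)),
              death_cycle = first_time(matrix(S == DEATH_STATE, n)))
  class(out) <- "dm_microsim"
  out
}

#' @export
print.dm_microsim <- function(x, ...) {
  cat(sprintf("<dm_microsim> %s, initiation age %d, n = %d, %d cycles\n",
              x$strategy, x$initiation_age, nrow(x$states),
              ncol(x$states) - 1L))
  invisible(x)
}

#' Deterministic cohort-proportion trace
#'
#' Expected-value evaluation of the same annual transition matrices: the
#' state-occupancy vector is propagated by matrix multiplication instead of
#' sampling.  Serves as the deterministic oracle against which the
#' microsimulation's empirical occupancy converges at rate 1/sqrt(n).
#'
#' @param initial named initial occupancy over [markov_states()] (or a
#'   single state label), summing to 1.
#' @param strategy strategy list or id string.
#' @param params `dm_parameters`.
#' @param initiation_age 25, 40 or 60.
#' @param life_table a `dm_life_table`.
#' @param group `"treated"`, `"column"` or `"others"` -- which rate set the
#'   traced cohort follows (see [run_microsim()]).
#' @return matrix of occupancy probabilities, `(horizon+1) x 14`.
#' @export
cohort_trace <- function(initial, strategy, params, initiation_age,
                         life_table = default_life_table(),
                         group = c("others", "treated", "column")) {
  group <- match.arg(group)
  if (is.character(strategy))
    strategy <- params$strategies[[match.arg(strategy, names(params$strategies))]]
  if (is.character(initial) && length(initial) == 1 && is.null(names(initial))) {
    v <- setNames(numeric(N_STATES), MARKOV_STATES)
    v[initial] <- 1
    initial <- v
  }
  v <- setNames(numeric(N_STATES), MARKOV_STATES)
  v[names(initial)] <- initial
  if (abs(sum(v) - 1) > 1e-9) stop("initial occupancy must sum to 1")
  H <- params$settings$horizon
  age_key <- as.character(initiation_age)
  qx <- qx_lookup(life_table, initiation_age + seq_len(H) - 1L)
  out <- matrix(NA_real_, H + 1L, N_STATES,
                dimnames = list(0:H, MARKOV_STATES))
  out[1, ] <- v
  for (t in seq_len(H)) {
    g <- group_rates(strategy, params, age_key, cycle = t, group = group)
    M <- transition_matrix(g$tunnel, g$post, g$ci, g$cm, params$shared, qx[t])
    v <- as.numeric(v %*% M)
    out[t + 1L, ] <- v
  }
  out
}

#' Validate all transition rows at start-up
#'
#' Builds every transition matrix used by a run (all strategies, all
#' initiation ages, tunnel and post-tunnel cycles, youngest and oldest
#' attained age) and checks each row sums to 1.
#'
#' @param params `dm_parameters`.
#' @param life_table a `dm_life_table`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_transitions <- function(params, life_table = default_life_table()) {
  for (arm in names(params$strategies)) {
    for (age in INITIATION_AGES) {
      H <- params$settings$horizon
      qx <- qx_lookup(life_table, age + c(0L, H - 1L))
      for (grp in c("treated", "column", "others")) {
        for (cyc in c(1L, params$settings$tunnel_length + 1L)) {
          for (q in qx) {
            g <- group_rates(params$strategies[[arm]], params,
                             as.character(age), cyc, grp)
            transition_matrix(g$tunnel, g$post, g$ci, g$cm,
                              params$shared, q)  # errors if invalid
          }
        }
      }
    }
  }
  invisible(TRUE)
}
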
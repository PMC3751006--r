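test_that("discounting and half-cycle weights match their definitions", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(0:10, 0), rep(1, 11))
  expect_equal(half_cycle_weight(0, 40), 0.5)
  expect_equal(half_cycle_weight(40, 40), 0.5)
  expect_equal(half_cycle_weight(1:39, 40), rep(1, 39))
  ## conservation: a constant accrual over H cycles at rate 0 totals a * H
  a <- 3.7; H <- 12
  expect_equal(sum(a * half_cycle_weight(0:H, H) * discount_factor(0:H, 0)),
               a * H)
  expect_equal(sum(a * half_cycle_weight(0:1, 1)), a)
})

test_that("the accumulator agrees with an independent trapezoid oracle", {
  ## oracle: trapezoid rule over the discounted accrual sequence,
  ## written without reference to the package's weight helpers
  trapezoid <- function(vals, rate) {
    disc <- vals / (1 + rate)^(seq_along(vals) - 1)
    sum((disc[-1] + disc[-length(disc)]) / 2)
  }
  set.seed(123)
  for (i in 1:100) {
    H <- sample(2:41, 1)
    vals <- runif(H + 1, 0, 100)
    rate <- runif(1, 0, 0.08)
    acc <- sum(vals * half_cycle_weight(0:H, H) * discount_factor(0:H, rate))
    expect_equal(acc, trapezoid(vals, rate), tolerance = 1e-9)
  }
})

test_that("per-subject accruals match closed-form oracles", {
  p <- default_parameters()
  H <- p$settings$horizon
  norm_state <- match("normal", markov_states())
  death_state <- match("death", markov_states())
  tunnel1 <- match("igt_t1", markov_states())

  ## always-normal subject: zero cost, QALYs equal the discounted
  ## half-cycle-weighted geometric series (about 23.5)
  S <- matrix(norm_state, 1, H + 1)
  acc <- accrue_trajectories(S, p, 25)
  r <- 1 / 1.03
  geom <- (1 - r^(H + 1)) / (1 - r) - 0.5 * (1 + r^H)
  expect_equal(acc$qalys, geom, tolerance = 1e-12)
  expect_equal(acc$cost, 0)
  expect_equal(acc$survival_years, H)

  ## discount rate 0: QALYs of an always-normal subject equal the
  ## half-cycle-weighted years alive
  p0 <- params_with(settings = list(discount_rate = 0))
  acc0 <- accrue_trajectories(S, p0, 25)
  expect_equal(acc0$qalys, acc0$survival_years)

  ## dead from cycle 0: only the screening cost, no QALYs, no years
  S <- matrix(death_state, 1, H + 1)
  acc <- accrue_trajectories(S, p, 25, screening_cost = 3)
  expect_equal(acc$cost, 3)
  expect_equal(acc$qalys, 0)
  expect_equal(acc$survival_years, 0)

  ## IGT subject intervened for exactly the six tunnel years (then reverts
  ## to normal): intervention cost component is the direct sum
  ## sum_{t=1..6} 371 * w(t) * 1.03^(-t)
  S <- matrix(norm_state, 1, H + 1)
  S[1, 1:6] <- tunnel1:(tunnel1 + 5)
  pduo <- p
  acc <- accrue_trajectories(S, pduo, 40, treated = TRUE,
                             intervention_cost = 371)
  oracle <- sum(371 * half_cycle_weight(1:6, H) * 1.03^-(1:6))
  expect_equal(acc$cost, oracle, tolerance = 1e-12)
})

test_that("a two-subject toy arm summarises to hand-computed values", {
  p <- params_with(settings = list(range_type = "minmax"))
  H <- p$settings$horizon
  ## build two hand-written subject outcome rows via accrue machinery
  states <- matrix(match("normal", markov_states()), 2, H + 1)
  states[2, ] <- match("onset_dm", markov_states())
  acc <- accrue_trajectories(states, p, 40)
  df <- cbind(acc, data.frame(
    subject = 1:2, treated = FALSE, baseline_igt = c(FALSE, FALSE),
    baseline_dm = c(FALSE, TRUE), incident_dm = FALSE,
    eligible = c(TRUE, TRUE),
    time_to_dm_censored = c(H, 0), time_to_complication_censored = c(H, H),
    death_cycle = NA_integer_))
  s <- summarize_outcomes(list(control = df, diet = df), p, 40)
  expect_equal(s$qalys, rep(mean(acc$qalys), 2))
  expect_equal(s$qalys_lo, rep(min(acc$qalys), 2))
  expect_equal(s$qalys_hi, rep(max(acc$qalys), 2))
  expect_equal(s$cost, rep(mean(acc$cost), 2))
  ## self-comparison: zero savings, zero increments, zero extra time
  d <- s[s$strategy == "diet", ]
  expect_equal(d$saving_vs_control, 0)
  expect_equal(d$increment_qalys_vs_control, 0)
  expect_true(is.na(d$extra_time_onset) || d$extra_time_onset == 0)
})

test_that("an identical strategy arm yields exactly zero deltas in a run", {
  run <- run_model(n = 3000, ages = 40, arms = c("screen_only", "control"),
                   seed = 21)
  so <- run$summary[run$summary$strategy == "screen_only", ]
  ## screening alone shares control dynamics: deltas are the screening cost
  expect_equal(so$extra_time_onset, 0)
  expect_equal(so$increment_qalys_vs_control, 0)
  expect_equal(so$saving_vs_control, -3 * run$params$screening$compliance,
               tolerance = 1e-9)
})

test_that("prevention postpones diabetes and saves costs at every age", {
  run <- run_model(n = 20000, ages = c(25, 40, 60), arms = c("diet", "control"),
                   seed = 31)
  d <- run$summary[run$summary$strategy == "diet", ]
  d <- d[order(d$initiation_age), ]
  ## diabetes-free and complication-free years gained, lower costs and more
  ## QALYs than control at every initiation age
  expect_true(all(d$extra_time_onset > 0))
  expect_true(all(d$extra_time_complication > 0))
  expect_true(all(d$increment_qalys_vs_control > 0))
  expect_true(all(d$saving_vs_control > 0))
  ## dearer treatment makes prevention save more
  p_up <- params_with(costs = list(onset_dm = 897 * 1.2, cvd = 2078 * 1.2,
                                   nephropathy = 1089 * 1.2,
                                   neuropathy = 1324 * 1.2,
                                   retinopathy = 888 * 1.2))
  run_up <- run_model(p_up, n = 20000, ages = 25, arms = c("diet", "control"),
                      seed = 31)
  expect_gt(run_up$summary$saving_vs_control[1],
            d$saving_vs_control[d$initiation_age == 25])
})
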
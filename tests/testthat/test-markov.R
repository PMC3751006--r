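test_that("every transition row sums to 1 across arms, ages and cycles", {
  p <- default_parameters()
  lt <- fixture_lt()
  expect_true(validate_transitions(p, lt))
  for (arm in strategy_ids()) {
    for (age in initiation_ages()) {
      for (st in markov_states()) {
        for (ii in c(TRUE, FALSE)) {
          r <- build_transition_row(st, arm, p, age,
                                    qx = qx_lookup_test(lt, age), ii)
          expect_equal(sum(r), 1, tolerance = 1e-12)
          expect_true(all(r >= 0))
        }
      }
    }
  }
})

test_that("transition rows match hand-computed published compositions", {
  p <- default_parameters()
  ## death is absorbing
  r <- build_transition_row("death", "control", p, 40, qx = 0.5)
  expect_equal(unname(r["death"]), 1)
  expect_equal(sum(r), 1)
  ## onset of diabetes, control arm, no background mortality:
  ## stay = 1 - (0.0675 + 0.001 + 0.005 + 0.0081)
  r <- build_transition_row("onset_dm", "control", p, 40, qx = 0)
  expect_equal(unname(r["onset_dm"]), 0.9184)
  expect_equal(unname(r["cvd"]), 0.0675)
  ## IGT tunnel under diet intervention at age 25, no background mortality
  r <- build_transition_row("igt_t2", "diet", p, 25, qx = 0,
                            in_intervention = TRUE)
  expect_equal(unname(r["onset_dm"]), 0.0290)
  expect_equal(unname(r["normal"]), 0.116)
  expect_equal(unname(r["igt_t3"]), 1 - 0.0290 - 0.116)
  ## survivors of tunnel year six move to post-tunnel IGT
  r <- build_transition_row("igt_t6", "control", p, 40, qx = 0)
  expect_gt(unname(r["igt_post"]), 0)
  expect_equal(unname(r["igt_t6"]), 0)
  ## competing mortality is applied first: qx appears in every living row
  r <- build_transition_row("normal", "control", p, 40, qx = 0.2)
  expect_equal(unname(r["death"]), 0.2)
  r <- build_transition_row("cvd", "control", p, 40, qx = 0.2)
  expect_equal(unname(r["death"]), 0.2 + 0.8 * 0.0087)
})

test_that("inverse-CDF stepping honours the fixed state ordering", {
  p <- default_parameters()
  row <- setNames(numeric(14), markov_states())
  row["death"] <- 1
  expect_equal(step(row, 0), "death")
  expect_equal(step(row, 0.999), "death")
  r <- build_transition_row("onset_dm", "control", p, 40, qx = 0.1)
  expect_equal(step(r, 0), "onset_dm")  # first nonzero-probability state
  ## empirical frequencies over many draws match the row within 3 SE
  set.seed(99)
  u <- runif(1e5)
  draws <- vapply(u, function(ui) step(r, ui), "")
  emp <- table(factor(draws, levels = markov_states())) / length(u)
  for (st in markov_states()) {
    se <- sqrt(r[st] * (1 - r[st]) / length(u))
    expect_lt(abs(emp[[st]] - r[[st]]), 3 * se + 1e-9)
  }
})

test_that("degenerate dynamics behave as limits dictate", {
  p <- frozen_params()
  co <- generate_test_cohort(300, "control", p, seed = 2)
  ## no transitions, no mortality: everyone keeps the initial health state
  ## (tunnel years still advance within the IGT class)
  sim <- run_microsim(co, "control", p, 25, flat_life_table(0), seed = 2)
  classes <- c(1, rep(2, 7), 3, 4, 5, 6, 7, 8)  # collapse tunnel states
  expect_true(all(matrix(classes[sim$states], nrow(sim$states)) ==
                    classes[sim$states[, 1]]))
  ## certain death: everyone dies at the first cycle, half a year lived
  sim <- run_microsim(co, "control", p, 25, flat_life_table(1), seed = 2)
  expect_true(all(sim$states[, 2] == match("death", markov_states())))
  out <- subject_outcomes(sim, p)
  expect_true(all(abs(out$survival_years - 0.5) < 1e-12))
})

test_that("tunnel states are traversed in order and never exceed six years", {
  p <- default_parameters()
  co <- generate_test_cohort(2000, "diet", p, seed = 8)
  sim <- run_microsim(co, "diet", p, 60, fixture_lt(), seed = 8)
  S <- sim$states
  tunnel_idx <- match(paste0("igt_t", 1:6), markov_states())
  in_tunnel <- matrix(S %in% tunnel_idx, nrow(S))
  ## a subject in tunnel k either leaves the tunnel or advances to k+1
  for (t in seq_len(ncol(S) - 1)) {
    now <- S[, t]
    nxt <- S[, t + 1]
    sel <- now %in% tunnel_idx & nxt %in% tunnel_idx
    if (any(sel)) expect_true(all(nxt[sel] == now[sel] + 1L))
  }
  ## nobody occupies a tunnel state for more than 6 cycles in a row
  ## (re-entering IGT later starts a fresh spell at tunnel 1)
  longest_spell <- apply(in_tunnel, 1, function(z) {
    r <- rle(z)
    max(c(0, r$lengths[r$values]))
  })
  expect_true(all(longest_spell <= 6))
})

test_that("microsimulation is reproducible and matches the cohort trace", {
  p <- default_parameters()
  lt <- fixture_lt()
  co <- generate_test_cohort(20000, "control", p, seed = 4)
  s1 <- run_microsim(co, "control", p, 40, lt, seed = 4)
  s2 <- run_microsim(co, "control", p, 40, lt, seed = 4)
  expect_identical(s1$states, s2$states)

  ## deterministic expected-value trace as oracle: start everyone in IGT
  co_igt <- co
  co_igt$state <- "igt"
  co_igt$receives_intervention <- FALSE
  sim <- run_microsim(co_igt, "control", p, 40, lt, seed = 4)
  tr <- cohort_trace("igt_t1", "control", p, 40, lt, group = "others")
  n <- nrow(co_igt)
  agg <- list(igt = 2:8, normal = 1, dm = 9, compl = 10:13, death = 14)
  for (t in c(2, 5, 11, 21, 41)) {
    for (g in names(agg)) {
      pr <- sum(tr[t, agg[[g]]])
      emp <- mean(sim$states[, t] %in% agg[[g]])
      se <- sqrt(pr * (1 - pr) / n)
      expect_lt(abs(emp - pr), 3 * se + 2 / n)
    }
  }
})

test_that("Monte-Carlo error of mean outcomes scales as 1 / sqrt(n)", {
  p <- default_parameters()
  lt <- fixture_lt()
  mean_qaly <- function(n, seed) {
    co <- generate_test_cohort(n, "control", p, seed)
    sim <- run_microsim(co, "control", p, 60, lt, seed)
    mean(subject_outcomes(sim, p)$qalys)
  }
  sds <- vapply(c(2500, 10000, 40000), function(n) {
    sd(vapply(1:8, function(s) mean_qaly(n, 100 + s), 0))
  }, 0)
  ## each quadrupling of n should roughly halve the SD
  expect_gt(sds[1] / sds[2], 1.2)
  expect_lt(sds[1] / sds[2], 3.3)
  expect_gt(sds[2] / sds[3], 1.2)
  expect_lt(sds[2] / sds[3], 3.3)
})
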
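test_that("the default grid covers the published one-way perturbations", {
  g <- default_scenario_grid()
  labels <- names(g)
  expect_true("normal to IGT incidence x3.0" %in% labels)
  expect_true("normal to IGT incidence x0.5" %in% labels)
  expect_true("screening compliance 60%" %in% labels)
  expect_true("IGT detection level 80%" %in% labels)
  expect_true(any(grepl("treatment costs x1.2", labels)))
  expect_true(any(grepl("discount rate", labels)))
  ## one parameter (group) at a time: every scenario has exactly one of
  ## multiplier/value and perturbs a single named assumption
  for (sc in g) {
    expect_true(xor(is.null(sc$multiplier), is.null(sc$value)))
  }
})

test_that("applying scenarios perturbs exactly the targeted values", {
  p <- default_parameters()
  g <- default_scenario_grid()
  p2 <- apply_scenario(p, g[["IGT to diabetes incidence x1.2"]])
  expect_equal(p2$strategies$control$igt_to_dm[["40"]], 0.1670 * 1.2)
  expect_equal(p2$strategies$diet$igt_to_dm[["25"]], 0.0290 * 1.2)
  expect_equal(p2$costs$onset_dm, p$costs$onset_dm)  # untouched
  p3 <- apply_scenario(p, g[["screening compliance 60%"]])
  expect_equal(p3$screening$compliance, 0.6)
  ## utility perturbation leaves the normal/death anchors alone
  p4 <- suppressWarnings(apply_scenario(p, g[["utilities x1.2"]]))
  expect_equal(unname(p4$utilities$table["normal", ]), c(1, 1, 1))
  expect_equal(unname(p4$utilities$table["death", ]), c(0, 0, 0))
  expect_equal(p4$utilities$table["onset_dm", "40"], min(1, 0.800 * 1.2))
  ## out-of-range products clamp with a warning per affected field
  big <- sens_scenario("igt x9", "strategies.*.igt_to_dm", multiplier = 9)
  w <- capture_warnings(apply_scenario(p, big))
  expect_true(any(grepl("clamped", w)))
})

test_that("an identity scenario reproduces the baseline bit for bit", {
  p <- default_parameters()
  grid <- list(identity = sens_scenario("identity", "costs.onset_dm",
                                        multiplier = 1))
  sens <- run_sensitivity(grid, p, fixture_lt(), ages = 25,
                          arms = "diet", n = 2000, seed = 17)
  base <- sens[sens$scenario == "baseline", ]
  idn <- sens[sens$scenario == "identity", ]
  expect_identical(base$saving_vs_control, idn$saving_vs_control)
  expect_identical(base$increment_qalys_vs_control,
                   idn$increment_qalys_vs_control)
})

test_that("savings fall monotonically with screening compliance", {
  p <- default_parameters()
  grid <- list(
    `compliance 80` = sens_scenario("compliance 80",
                                    "screening.compliance", value = 0.8),
    `compliance 60` = sens_scenario("compliance 60",
                                    "screening.compliance", value = 0.6))
  sens <- run_sensitivity(grid, p, fixture_lt(), ages = c(25, 40),
                          arms = c("diet", "exercise"), n = 20000, seed = 13)
  for (arm in c("diet", "exercise")) {
    for (age in c(25, 40)) {
      v <- sens[sens$strategy == arm & sens$initiation_age == age, ]
      sv <- v$saving_vs_control[match(c("baseline", "compliance 80",
                                        "compliance 60"), v$scenario)]
      expect_true(all(diff(sv) < 0), info = paste(arm, age))
    }
  }
})

test_that("savings scale linearly in treatment costs when they are the only costs", {
  ## toy: free screening and intervention, so the control-vs-diet cost
  ## difference is purely treatment spending and doubles with it
  p <- params_with(costs = list(screening = 0),
                   strategies = list(diet = list(annual_intervention_cost = 0)))
  grid <- list(double = sens_scenario(
    "double", c("costs.onset_dm", "costs.cvd", "costs.nephropathy",
                "costs.neuropathy", "costs.retinopathy"), multiplier = 2))
  sens <- run_sensitivity(grid, p, fixture_lt(), ages = 40, arms = "diet",
                          n = 8000, seed = 9)
  base <- sens$saving_vs_control[sens$scenario == "baseline"]
  dbl <- sens$saving_vs_control[sens$scenario == "double"]
  expect_equal(dbl, 2 * base, tolerance = 1e-9)
})

test_that("the compliance pivot has the strategy-by-age layout", {
  p <- default_parameters()
  grid <- default_scenario_grid()[c("screening compliance 80%",
                                    "screening compliance 60%")]
  sens <- run_sensitivity(grid, p, fixture_lt(), ages = c(25, 40, 60),
                          arms = c("diet", "exercise", "duo", "screen_only"),
                          n = 1500, seed = 23)
  piv <- pivot_savings(sens)
  expect_equal(nrow(piv), 4)      # four prevention strategies
  expect_equal(ncol(piv), 1 + 3 * 3)  # baseline + 80% + 60% per age
})
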
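test_that("power-family spending matches its closed form and domain", {
  expect_equal(power_spending(1, 2.5, 0.025), 0.025)
  expect_equal(power_spending(0.5, 1, 0.025), 0.0125)
  expect_equal(power_spending(0.5, 3, 0.025), 0.003125)
  t <- seq(0, 1, 0.05)
  for (g in c(0.75, 1.5, 3))
    expect_true(all(diff(power_spending(t, g, 0.025)) >= 0))
  expect_error(power_spending(-0.1, 1, 0.025), "\\[0, 1\\]")
  expect_error(power_spending(1.2, 1, 0.025), "\\[0, 1\\]")
})

test_that("single-look design reduces to the fixed-design critical value", {
  d <- compute_boundaries(look_schedule(1), spending_spec(0.025, 0.1))
  expect_equal(d$efficacy_z[1], qnorm(0.975), tolerance = 1e-6)
  expect_equal(d$inflation_factor, 1, tolerance = 1e-9)
  expect_true(all(is.na(d$futility_z)))
})

test_that("late spending gives O'Brien-Fleming-type boundary monotonicity", {
  sch <- look_schedule(c(0.5, 1), 0.5)
  d <- compute_boundaries(sch, spending_spec(0.025, 0.1, gamma_alpha = 3))
  expect_true(d$efficacy_z[1] > d$efficacy_z[2])
  # gamma monotonicity: larger gamma_alpha -> higher early boundary, final
  # boundary closer to the fixed-design critical value
  zs <- sapply(c(1, 2, 3), function(g) {
    compute_boundaries(sch, spending_spec(0.025, 0.1, gamma_alpha = g))$efficacy_z
  })
  expect_true(all(diff(zs[1, ]) > 0))
  expect_true(all(diff(abs(zs[2, ] - qnorm(0.975))) < 0))
})

test_that("Schoenfeld event formula matches its closed form", {
  expect_identical(required_events(0.5, 0.025, 0.1, 1), 88L)
  expect_equal(required_events(0.5, 0.025, 0.1, 1),
               ceiling(4 * (qnorm(0.975) + qnorm(0.9))^2 / log(2)^2))
  expect_error(required_events(1), "design_hr = 1")
  # halving |log HR| quadruples D (before rounding)
  d1 <- 4 * (qnorm(0.975) + qnorm(0.9))^2 / log(0.5)^2
  expect_equal(required_events(exp(log(0.5) / 2)), ceiling(4 * d1))
  # divergence toward the null
  expect_gt(required_events(0.999), 1e6)
})

test_that("boundaries reproduce the spending functions by construction", {
  for (seed in c(11, 12, 13, 14, 15)) {
    d <- random_grid_design(seed)
    cp0 <- crossing_probabilities(d, 0, ignore_futility = TRUE)
    eff <- which(d$efficacy)
    # cumulative alpha spend at efficacy looks (final exhausts the budget)
    target <- 0.025 * d$frac[eff]^d$spec$gamma_alpha
    target[length(target)] <- 0.025
    expect_equal(cumsum(cp0$p_efficacy)[eff], target, tolerance = 1e-4)
    # cumulative beta spend at futility looks under the design drift
    cpd <- crossing_probabilities(d, d$drift)
    fut <- which(d$futility)
    expect_equal(cumsum(cpd$p_futility)[fut],
                 0.1 * d$frac[fut]^d$spec$gamma_beta, tolerance = 1e-4)
    # nonbinding guarantee and probability bookkeeping
    expect_lte(attr(cp0, "total_efficacy"), 0.025 + 1e-4)
    expect_lte(attr(crossing_probabilities(d, 0), "total_efficacy"),
               0.025 + 1e-4)
    expect_equal(attr(cpd, "total_efficacy") + attr(cpd, "total_futility"),
                 1, tolerance = 1e-6)
  }
})

test_that("recursive integration agrees with the Monte-Carlo z-process oracle", {
  d <- compute_boundaries(look_schedule(c(1 / 3, 2 / 3, 1), 2 / 3),
                          paper_spec(), fixed_D = 90)
  for (drift in c(0, 2.5)) {
    cp <- crossing_probabilities(d, drift)
    mc <- mc_crossing_oracle(d, drift, 2e5, seed = 99 + drift)
    tol <- 3 * mc_se(pmax(mc$p_eff, 0.005), 2e5)
    expect_true(all(abs(cp$p_efficacy - mc$p_eff) < tol))
    tol <- 3 * mc_se(pmax(mc$p_fut, 0.005), 2e5)
    expect_true(all(abs(cp$p_futility - mc$p_fut) < tol))
  }
})

test_that("crossing probabilities behave at the drift extremes", {
  d <- random_grid_design(21)
  expect_equal(attr(crossing_probabilities(d, 0, ignore_futility = TRUE),
                    "total_efficacy"), 0.025, tolerance = 1e-4)
  cp <- crossing_probabilities(d, 40)
  first_eff <- which(d$efficacy)[1]
  expect_gt(cp$p_efficacy[first_eff], 0.999)
})

test_that("event inflation restores power and is 1 for the fixed design", {
  expect_equal(inflate_max_events(66, look_schedule(1),
                                  paper_spec())$inflation_factor, 1)
  sch <- look_schedule(c(0.3, 0.4, 0.5, 0.6), 0.6)
  inf <- inflate_max_events(66, sch, paper_spec())
  expect_gt(inf$inflation_factor, 1)
  d <- inf$design
  expect_equal(d$events[length(d$events)], inf$max_events)
  expect_gte(attr(crossing_probabilities(d, d$drift), "total_efficacy"),
             0.9 - 1e-3)
  # simulation oracle for power recovery
  mc <- mc_crossing_oracle(d, d$drift, 2e5, seed = 7)
  expect_gte(mc$total_eff, 0.9 - 3 * mc_se(0.9, 2e5))
})

test_that("boundary invariants hold across the design", {
  d <- compute_boundaries(look_schedule(c(0.3, 0.4, 0.5, 0.6), 0.6),
                          paper_spec(), fixed_D = 66)
  shared <- which(d$efficacy & d$futility)
  expect_true(all(d$efficacy_z[shared] > d$futility_z[shared]))
  expect_true(all(diff(d$events) > 0))
  expect_gte(d$inflation_factor, 1)
})

test_that("designs serialize to JSON and CSV and round-trip", {
  d <- compute_boundaries(look_schedule(c(0.5, 1), 0.5), paper_spec(),
                          fixed_D = 66)
  path <- withr::local_tempfile(fileext = ".json")
  write_design(d, path)
  d2 <- read_design(path)
  expect_equal(d2$efficacy_z, d$efficacy_z, tolerance = 1e-12)
  expect_equal(d2$futility_z, d$futility_z, tolerance = 1e-12)
  expect_identical(d2$max_events, d$max_events)
  expect_equal(d2$frac, d$frac)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(d, csv)
  tab <- read.csv(csv)
  expect_named(tab, c("look", "information_fraction", "events", "efficacy_z",
                      "futility_z", "cumulative_alpha_spent",
                      "cumulative_beta_spent"))
  expect_equal(nrow(tab), 2L)
})
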
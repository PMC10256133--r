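test_that("default grid enumerates the full candidate set", {
  schemes <- enumerate_schemes(scheme_grid(), paper_spec())
  # sets of 4 or 5 futility looks from 7 fractions, each containing 0.6,
  # crossed with 10 beta and 5 alpha exponents
  expect_equal(nrow(schemes), (choose(6, 3) + choose(6, 4)) * 10 * 5)
  expect_equal(nrow(schemes), 1750L)
  expect_true(all(vapply(schemes$fractions,
                         function(f) any(abs(f - 0.6) < 1e-9), TRUE)))
  expect_false(anyDuplicated(paste(schemes$timing, schemes$gamma_alpha,
                                   schemes$gamma_beta)) > 0)
  # stable ordering
  schemes2 <- enumerate_schemes(scheme_grid(), paper_spec())
  expect_identical(schemes$timing, schemes2$timing)
})

test_that("degenerate grids enumerate correctly and invalid grids fail", {
  g1 <- scheme_grid(n_futility_looks = 4L,
                    candidate_fractions = c(0.3, 0.4, 0.5, 0.6),
                    gamma_beta_grid = 2.5, gamma_alpha_grid = 2.5)
  expect_equal(nrow(enumerate_schemes(g1, paper_spec())), 1L)
  expect_error(scheme_grid(candidate_fractions = c(0.3, 0.5)),
               "superiority_fraction")
  expect_error(scheme_grid(gamma_beta_grid = numeric(0)), "nonempty")
})

test_that("duration exclusion follows the expected-duration rule", {
  assume <- toy_assumptions()
  g <- scheme_grid(n_futility_looks = 4L,
                   candidate_fractions = c(0.3, 0.4, 0.5, 0.6, 0.7),
                   gamma_beta_grid = c(0.75, 3), gamma_alpha_grid = c(2, 3))
  schemes <- enumerate_schemes(g, paper_spec(), fixed_D = 66)
  schemes <- apply_duration_exclusion(schemes, assume)
  expect_true(all(c("max_events", "max_duration", "excluded") %in%
                  names(schemes)))
  dur_fixed <- attr(schemes, "fixed_design_duration")
  expect_equal(schemes$excluded, schemes$max_duration > 1.1 * dur_fixed)
  # monotone in max_events: if a larger design is retained, so is a smaller
  ord <- order(schemes$max_events)
  expect_true(all(diff(schemes$max_duration[ord]) >= -1e-9))
  # an uninflated scheme can never be excluded
  single <- enumerate_schemes(
    scheme_grid(n_futility_looks = 1L, candidate_fractions = 0.6,
                gamma_beta_grid = 2.5, gamma_alpha_grid = 2.5),
    paper_spec(), fixed_D = 66)
  single <- apply_duration_exclusion(single, assume)
  expect_false(any(single$excluded[single$max_events == 66]))
})

test_that("evaluation with one replicate equals the single trial outcome", {
  assume <- toy_assumptions()
  design <- compute_boundaries(look_schedule(c(0.3, 0.5, 0.6), 0.6),
                               paper_spec(), fixed_D = 66)
  pr <- mixture_prior(0.071, log(0.45), 0.335, 1.06)
  ev <- evaluate_schemes(list(design), pr, assume, n_replicates = 1,
                         seed = 17)
  # replay the replicate by hand with the same stream
  set.seed(optinterim:::.replicate_seed(17, 1))
  eff <- sample_effect(pr, 1)
  tr <- simulate_trial(assume, eff$log_hr)
  dec <- apply_boundaries(run_looks(tr, design), design)
  expect_equal(ev$summary$mean_duration, dec$stop_time)
  expect_equal(ev$summary$p_reject, as.numeric(dec$rejected))
})

test_that("common random numbers make evaluations order-invariant", {
  assume <- toy_assumptions()
  d1 <- compute_boundaries(look_schedule(c(0.3, 0.5, 0.6), 0.6),
                           paper_spec(), fixed_D = 66)
  d2 <- compute_boundaries(look_schedule(c(0.4, 0.6, 0.8), 0.6),
                           paper_spec(2, 1), fixed_D = 66)
  pr <- mixture_prior(0.071, log(0.45), 0.335, 1.06)
  ev_a <- evaluate_schemes(list(d1, d2), pr, assume, 40, seed = 3)
  ev_b <- evaluate_schemes(list(d2, d1), pr, assume, 40, seed = 3)
  expect_equal(ev_a$summary$mean_duration,
               rev(ev_b$summary$mean_duration))
  expect_equal(ev_a$summary$mean_n, rev(ev_b$summary$mean_n))
  # and reproducible under the same seed
  ev_c <- evaluate_schemes(list(d1, d2), pr, assume, 40, seed = 3)
  expect_identical(ev_a$summary, ev_c$summary)
  # stop probabilities are a distribution per scheme
  agg <- tapply(ev_a$stop_probs$probability, ev_a$stop_probs$scheme, sum)
  expect_equal(as.numeric(agg), c(1, 1))
})

test_that("selection minimizes the criterion with deterministic tie-breaks", {
  assume <- toy_assumptions()
  g <- scheme_grid(n_futility_looks = 4L,
                   candidate_fractions = c(0.3, 0.4, 0.5, 0.6),
                   gamma_beta_grid = c(1, 2.5), gamma_alpha_grid = 2.5)
  schemes <- enumerate_schemes(g, paper_spec(), fixed_D = 66)
  pr <- mixture_prior(0.071, log(0.45), 0.335, 1.06)
  ev <- evaluate_schemes(schemes, pr, assume, 60, seed = 5)
  sel <- select_optimal(ev, "duration")
  expect_equal(sel$optimum$mean_duration, min(ev$summary$mean_duration))
  expect_true(all(sel$ranking$mean_duration >= sel$optimum$mean_duration))
  # other criteria select by their own column
  sel_n <- select_optimal(ev, "sample_size")
  expect_equal(sel_n$optimum$mean_n, min(ev$summary$mean_n))
  # a single candidate returns itself
  one <- evaluate_schemes(list(attr(schemes, "designs")[[1]]), pr, assume,
                          10, seed = 5)
  expect_equal(select_optimal(one)$optimum$scheme, 1)
  # all-excluded raises
  ev$summary$excluded <- TRUE
  expect_error(select_optimal(ev), "all schemes were excluded")
})

test_that("degenerate boundaries mean the trial always runs to the end", {
  assume <- toy_assumptions()
  design <- compute_boundaries(look_schedule(c(0.3, 0.6), 0.6),
                               paper_spec(), fixed_D = 66)
  design$efficacy_z[design$efficacy] <- Inf
  design$futility_z[design$futility] <- -Inf
  pr <- mixture_prior(0.071, log(0.45), 0.335, 1.06)
  ev <- evaluate_schemes(list(design), pr, assume, 25, seed = 9)
  # never stops early: duration equals the time to the final event target
  durations <- vapply(1:25, function(i) {
    set.seed(optinterim:::.replicate_seed(9, i))
    eff <- sample_effect(pr, 1)
    tr <- simulate_trial(assume, eff$log_hr)
    calendar_time_of_event(tr, design$max_events)
  }, 0)
  expect_equal(ev$summary$mean_duration, mean(durations))
  expect_equal(ev$summary$p_reject, 0)
})

test_that("under a harmful effect interim schemes shorten the trial", {
  assume <- toy_assumptions()
  g <- scheme_grid(n_futility_looks = 4L,
                   candidate_fractions = c(0.3, 0.4, 0.5, 0.6),
                   gamma_beta_grid = 2.5, gamma_alpha_grid = 2.5)
  schemes <- enumerate_schemes(g, paper_spec(), fixed_D = 66)
  ev <- evaluate_schemes(schemes, NULL, assume, 150, seed = 21,
                         fixed_log_hr = log(1.8))
  fixed <- evaluate_schemes(list(fixed_design(assume)), NULL, assume, 150,
                            seed = 21, fixed_log_hr = log(1.8))
  expect_lt(ev$summary$mean_duration, fixed$summary$mean_duration)
})
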
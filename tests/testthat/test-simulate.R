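test_that("simulated arms follow the configured Weibull medians under PH", {
  assume <- trial_assumptions(n_total = 40000, accrual_duration = 1,
                              median_control = 28.9,
                              design_hr = (28.9 / 43.4)^2, weibull_shape = 2)
  tr <- simulate_trial(assume, log(assume$design_hr), seed = 1)
  med_c <- median(tr$time[tr$arm == 0])
  med_t <- median(tr$time[tr$arm == 1])
  expect_equal(med_c, 28.9, tolerance = 0.01)
  # PH through the Weibull scale: HR = (median_c / median_t)^rho
  expect_equal(med_t, 43.4, tolerance = 0.01)
  # null case: arms indistinguishable
  tr0 <- simulate_trial(assume, 0, seed = 2)
  ks <- suppressWarnings(ks.test(tr0$time[tr0$arm == 0],
                                 tr0$time[tr0$arm == 1]))
  expect_gt(ks$p.value, 0.01)
})

test_that("trial layout respects accrual and allocation", {
  assume <- toy_assumptions()
  tr <- simulate_trial(assume, 0, seed = 3)
  expect_equal(nrow(tr), assume$n_total)
  expect_true(all(tr$entry >= 0 & tr$entry <= assume$accrual_duration))
  expect_true(all(tr$time > 0))
  expect_equal(sum(tr$arm), assume$n_total / 2)
  r2 <- trial_assumptions(90, 12, 21.4, 0.45, allocation_ratio = 2)
  expect_equal(sum(simulate_trial(r2, 0, seed = 1)$arm), 60)
  expect_identical(simulate_trial(assume, -0.5, seed = 9),
                   simulate_trial(assume, -0.5, seed = 9))
})

test_that("calendar event times are ordered and capped ranks warn", {
  tr <- simulate_trial(toy_assumptions(n_total = 50), 0, seed = 4)
  tk <- calendar_time_of_event(tr, 1:50)
  expect_equal(tk[1], min(tr$calendar))
  expect_true(all(diff(tk) >= 0))
  expect_warning(out <- calendar_time_of_event(tr, 51), "information cap")
  expect_true(is.na(out))
  expect_error(calendar_time_of_event(tr, 0), ">= 1")
})

test_that("log-rank agrees with the survival package on censored data", {
  assume <- toy_assumptions(n_total = 80)
  for (seed in 1:5) {
    tr <- simulate_trial(assume, log(0.6), seed = seed)
    tau <- calendar_time_of_event(tr, 40)
    lr <- logrank_z(tr, tau)
    inx <- tr$entry <= tau
    fu <- tau - tr$entry[inx]
    df <- data.frame(time = pmin(tr$time[inx], fu),
                     status = as.integer(tr$time[inx] <= fu),
                     arm = tr$arm[inx])
    sd <- survival::survdiff(survival::Surv(time, status) ~ arm, df)
    expect_equal(lr$z^2, sd$chisq, tolerance = 1e-8)
    # sign: z > 0 iff treated arm has fewer deaths than expected
    expect_equal(sign(lr$z), sign(sd$exp[2] - sd$obs[2]))
    expect_equal(lr$events, sum(df$status))
  }
})

test_that("log-rank sign convention and error cases", {
  assume <- toy_assumptions(n_total = 60)
  tr <- simulate_trial(assume, log(0.05), seed = 6)  # very strong benefit
  expect_gt(logrank_z(tr, max(tr$calendar))$z, 3)
  expect_error(logrank_z(tr, 1e-12), "no events|no patients")
})

test_that("null log-rank z is standard normal across replicates", {
  assume <- toy_assumptions(n_total = 150)
  z <- vapply(1:2000, function(i) {
    tr <- simulate_trial(assume, 0, seed = 10000 + i)
    logrank_z(tr, calendar_time_of_event(tr, 100))$z
  }, 0)
  expect_lt(abs(mean(z)), 0.07)         # 3 / sqrt(2000) ~ 0.067
  expect_gt(var(z), 0.9)
  expect_lt(var(z), 1.1)
})

test_that("z drifts like the Schoenfeld approximation", {
  hr <- 0.85
  n <- 600
  assume <- trial_assumptions(n, 6, 21.4, hr)
  z <- vapply(1:400, function(i) {
    tr <- simulate_trial(assume, log(hr), seed = 20000 + i)
    logrank_z(tr, max(tr$calendar))$z
  }, 0)
  expected <- -log(hr) * sqrt(n) / 2
  expect_equal(mean(z), expected,
               tolerance = (3 / sqrt(400) + 0.05 * expected) / expected)
})

test_that("run_looks hits exact event targets and is recomputation-stable", {
  assume <- toy_assumptions()
  design <- compute_boundaries(look_schedule(c(0.3, 0.5, 0.6), 0.6),
                               paper_spec(), fixed_D = 66)
  tr <- simulate_trial(assume, log(0.45), seed = 8)
  traj <- run_looks(tr, design)
  expect_s3_class(traj, "z_trajectory")
  expect_equal(traj$events, ceiling(design$frac * design$max_events))
  expect_equal(traj$events_observed, traj$events)
  expect_true(all(diff(traj$calendar) > 0))
  # one-pass vs per-look recomputation equivalence
  z2 <- vapply(traj$calendar, function(tau) logrank_z(tr, tau)$z, 0)
  expect_identical(traj$z, z2)
  # single-look design
  fd <- fixed_design(assume)
  expect_equal(nrow(run_looks(tr, fd)), 1L)
})

test_that("unreachable event targets are flagged as capped", {
  assume <- toy_assumptions(n_total = 50)
  design <- compute_boundaries(look_schedule(c(0.5, 1), 0.5), paper_spec(),
                               fixed_D = 60)  # inflated D > 50 patients
  tr <- simulate_trial(assume, 0, seed = 11)
  traj <- run_looks(tr, design)
  expect_true(traj$capped[nrow(traj)])
  expect_equal(traj$calendar[nrow(traj)], max(tr$calendar))
})

test_that("expected event curve matches Monte-Carlo time to target", {
  assume <- toy_assumptions()
  D <- 70
  tmc <- vapply(1:300, function(i) {
    tr <- simulate_trial(assume, log(0.45), seed = 30000 + i)
    calendar_time_of_event(tr, D)
  }, 0)
  tdet <- expected_time_to_events(D, assume, log(0.45))
  expect_equal(tdet, mean(tmc), tolerance = 0.02)
  # monotone and capped
  expect_gt(expected_time_to_events(80, assume), tdet)
  expect_warning(res <- expected_time_to_events(500, assume),
                 "information cap")
  expect_identical(res, Inf)
})

test_that("full pipeline calibrates type-I error and power", {
  assume <- trial_assumptions(400, 12, 21.4, 0.7, alpha = 0.025,
                              power = 0.9)
  design <- compute_boundaries(look_schedule(c(0.3, 0.5, 0.6), 0.6),
                               paper_spec(),
                               fixed_D = required_events(0.7))
  run_one <- function(i, log_hr) {
    tr <- simulate_trial(assume, log_hr, seed = 40000 + i)
    apply_boundaries(run_looks(tr, design), design)$rejected
  }
  n_rep <- 1500
  rej0 <- mean(vapply(1:n_rep, run_one, TRUE, log_hr = 0))
  expect_lte(rej0, 0.025 + 3 * mc_se(0.025, n_rep))
  rej1 <- mean(vapply(1:n_rep, run_one, TRUE, log_hr = log(0.7)))
  expect_gt(rej1, 0.9 - 3 * mc_se(0.9, n_rep) - 0.015)
})

test_that("trials and trajectories export as CSV", {
  tr <- simulate_trial(toy_assumptions(n_total = 30), 0, seed = 12)
  f <- withr::local_tempfile(fileext = ".csv")
  export_csv(tr, f, at_time = 20)
  df <- read.csv(f)
  expect_named(df, c("patient_id", "arm", "entry_time", "time_to_event",
                     "event_flag", "censor_time"))
  expect_true(all(df$time_to_event <= 20))
  design <- fixed_design(toy_assumptions(n_total = 30))
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_csv(run_looks(tr, design), f2)
  expect_true("z" %in% names(read.csv(f2)))
})
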
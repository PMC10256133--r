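# Independent Monte-Carlo oracle for sequential boundary crossing: simulates
# the correlated z-process directly from its independent B-value increments
# (no shared code with the package's recursive integration).
mc_crossing_oracle <- function(design, drift, n_rep, seed,
                               ignore_futility = FALSE) {
  set.seed(seed)
  fr <- design$frac
  K <- length(fr)
  dt <- diff(c(0, fr))
  inc <- matrix(stats::rnorm(n_rep * K, mean = rep(drift * dt, each = n_rep),
                             sd = rep(sqrt(dt), each = n_rep)), n_rep, K)
  B <- inc
  for (k in seq_len(K)[-1]) B[, k] <- B[, k - 1] + inc[, k]
  Z <- sweep(B, 2, sqrt(fr), "/")
  up <- ifelse(design$efficacy & is.finite(design$efficacy_z),
               design$efficacy_z, Inf)
  lo <- if (ignore_futility) rep(-Inf, K)
        else ifelse(design$futility & is.finite(design$futility_z),
                    design$futility_z, -Inf)
  alive <- rep(TRUE, n_rep)
  p_eff <- p_fut <- numeric(K)
  for (k in seq_len(K)) {
    e <- alive & Z[, k] > up[k]
    f <- alive & Z[, k] < lo[k]
    p_eff[k] <- mean(e)
    p_fut[k] <- mean(f)
    alive <- alive & !e & !f
  }
  p_fut[K] <- p_fut[K] + mean(alive)  # final non-rejection
  list(p_eff = p_eff, p_fut = p_fut,
       total_eff = sum(p_eff), se = sqrt(0.25 / n_rep))
}

# Monte-Carlo standard error for a proportion estimate
mc_se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-12) / n)

# small shared fixtures
toy_assumptions <- function(n_total = 120, accrual = 24) {
  trial_assumptions(n_total = n_total, accrual_duration = accrual,
                    median_control = 21.4, design_hr = 0.45,
                    weibull_shape = 2, alpha = 0.025, power = 0.9)
}

paper_spec <- function(ga = 2.5, gb = 2.5) {
  spending_spec(0.025, 0.1, gamma_alpha = ga, gamma_beta = gb)
}

# draw a random scheme from the default search grid
random_grid_design <- function(seed, fixed_D = 66) {
  set.seed(seed)
  g <- scheme_grid()
  nf <- sample(g$n_futility_looks, 1)
  fr <- sort(c(0.6, sample(setdiff(g$candidate_fractions, 0.6), nf - 1)))
  sp <- spending_spec(0.025, 0.1,
                      gamma_alpha = sample(g$gamma_alpha_grid, 1),
                      gamma_beta = sample(g$gamma_beta_grid, 1))
  compute_boundaries(look_schedule(fr, 0.6), sp, fixed_D = fixed_D)
}
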
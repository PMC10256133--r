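#' Trial planning assumptions
#'
#' The planning inputs of an event-driven two-arm survival trial: enrollment,
#' control-arm survival, the design effect, and the error rates used for
#' sizing.
#'
#' @param n_total planned number of randomized patients.
#' @param accrual_duration accrual period (months); enrollment is uniform.
#' @param median_control control-arm median survival (months).
#' @param design_hr design hazard ratio (treated vs control).
#' @param allocation_ratio treated:control allocation ratio.
#' @param weibull_shape Weibull shape rho of the event-time distribution.
#' @param alpha type-I error (one-sided unless `sided = 2`).
#' @param power target power at the design hazard ratio.
#' @param sided 1 or 2.
#' @return an object of class `trial_assumptions`.
#' @export
trial_assumptions <- function(n_total, accrual_duration, median_control,
                              design_hr, allocation_ratio = 1,
                              weibull_shape = 2, alpha = 0.025, power = 0.9,
                              sided = 1L) {
  .check_number(n_total, "n_total", 2, Inf, integer = TRUE)
  .check_number(accrual_duration, "accrual_duration", 0, Inf, TRUE)
  .check_number(median_control, "median_control", 0, Inf, TRUE)
  .check_number(design_hr, "design_hr", 0, Inf, TRUE)
  .check_number(allocation_ratio, "allocation_ratio", 0, Inf, TRUE)
  .check_number(weibull_shape, "weibull_shape", 0, Inf, TRUE)
  .check_number(alpha, "alpha", 0, 1, TRUE, TRUE)
  .check_number(power, "power", 0, 1, TRUE, TRUE)
  structure(list(n_total = as.integer(n_total),
                 accrual_duration = accrual_duration,
                 median_control = median_control, design_hr = design_hr,
                 allocation_ratio = allocation_ratio,
                 weibull_shape = weibull_shape, alpha = alpha, power = power,
                 sided = as.integer(sided)),
            class = "trial_assumptions")
}

#' @export
print.trial_assumptions <- function(x, ...) {
  cat(sprintf(
    "Trial assumptions: n = %d (r = %g), accrual %g mo, control median %g mo (rho = %g)\n  design HR = %g, alpha = %g (%d-sided), power = %g\n",
    x$n_total, x$allocation_ratio, x$accrual_duration, x$median_control,
    x$weibull_shape, x$design_hr, x$alpha, x$sided, x$power))
  invisible(x)
}

.fixed_events <- function(assumptions, log_hr = NULL) {
  hr <- if (is.null(log_hr)) assumptions$design_hr else exp(log_hr)
  required_events(hr, assumptions$alpha, 1 - assumptions$power,
                  assumptions$allocation_ratio, assumptions$sided)
}

# drift of the z-statistic at D events for a given log-HR
.drift_at <- function(log_hr, D, allocation_ratio = 1) {
  r <- allocation_ratio
  -log_hr * sqrt(D * r) / (1 + r)
}

#' Simulate one event-driven two-arm survival trial
#'
#' Event times are Weibull with the configured shape; the treatment effect is
#' injected through the scale so hazards are exactly proportional
#' (`S_treated = S_control^HR`, scale `lambda_c * HR^(-1/rho)`). Entry times
#' are uniform over the accrual period and there is no loss to follow-up.
#'
#' @param assumptions a [trial_assumptions()].
#' @param log_hr true log hazard ratio for this trial.
#' @param seed optional integer seed.
#' @return an object of class `sim_trial`: a data frame with columns `id`,
#'   `arm` (0 control / 1 treated), `entry`, `time` (time to event since
#'   entry) and `calendar` (entry + time).
#' @export
simulate_trial <- function(assumptions, log_hr, seed = NULL) {
  stopifnot(inherits(assumptions, "trial_assumptions"))
  .check_number(log_hr, "log_hr")
  if (!is.null(seed)) set.seed(seed)
  n <- assumptions$n_total
  r <- assumptions$allocation_ratio
  rho <- assumptions$weibull_shape
  n_t <- round(n * r / (1 + r))
  arm <- sample(rep(c(1L, 0L), c(n_t, n - n_t)))
  entry <- stats::runif(n, 0, assumptions$accrual_duration)
  lam_c <- assumptions$median_control / log(2)^(1 / rho)
  lam <- lam_c * exp(-log_hr / rho)^(arm)      # lambda_c * HR^(-1/rho) if treated
  time <- stats::rweibull(n, shape = rho, scale = lam)
  out <- data.frame(id = seq_len(n), arm = arm, entry = entry, time = time,
                    calendar = entry + time)
  attr(out, "assumptions") <- assumptions
  attr(out, "log_hr") <- log_hr
  class(out) <- c("sim_trial", "data.frame")
  out
}

#' Calendar time at which the k-th event occurs
#'
#' @param trial a [simulate_trial()] result.
#' @param k event rank (vectorized). Ranks beyond the achievable number of
#'   events return `NA` with a warning (the "information cap": the trial can
#'   never accumulate that many events).
#' @return calendar time(s) of the k-th event since the first enrollment.
#' @export
calendar_time_of_event <- function(trial, k) {
  stopifnot(inherits(trial, "sim_trial"))
  if (any(k < 1)) stop("event rank must be >= 1")
  cal <- sort(trial$calendar)
  out <- rep(NA_real_, length(k))
  ok <- k <= length(cal)
  out[ok] <- cal[k[ok]]
  if (any(!ok))
    warning("information cap: requested event rank exceeds achievable events")
  out
}

# core log-rank computation on (time, status, arm); z > 0 favors the treated
# arm (fewer treated deaths than expected under the null)
.logrank_core <- function(time, status, arm) {
  d_tot <- sum(status)
  if (d_tot == 0L) stop("log-rank undefined: no events at the analysis time")
  o <- order(time)
  tt <- time[o]; ss <- status[o]; aa <- arm[o]
  first <- !duplicated(tt)
  m <- length(tt)
  n_at <- (m:1)[first]                          # total at risk at unique times
  n1_at <- rev(cumsum(rev(aa)))[first]          # treated at risk
  d <- rowsum(ss, tt, reorder = FALSE)[, 1]     # deaths per unique time
  d1 <- rowsum(ss * aa, tt, reorder = FALSE)[, 1]
  keep <- d > 0
  n_at <- n_at[keep]; n1_at <- n1_at[keep]; d <- d[keep]; d1 <- d1[keep]
  p1 <- n1_at / n_at
  U <- sum(d1 - d * p1)
  vterm <- d * p1 * (1 - p1) * (n_at - d) / pmax(n_at - 1, 1)
  vterm[n_at <= 1] <- 0
  V <- sum(vterm)
  if (V <= 0) stop("log-rank undefined: zero variance")
  list(z = -U / sqrt(V), events = d_tot, log_hr = U / V)
}

#' Log-rank test at an analysis calendar time
#'
#' Administratively censors the trial at `at_time` (patients not yet enrolled
#' are excluded; follow-up is truncated at `at_time - entry`) and computes
#' the standard log-rank statistic. Sign convention: `z > 0` favors the
#' treated arm (hazard reduction).
#'
#' @param trial a [simulate_trial()] result.
#' @param at_time analysis calendar time (months since first enrollment).
#' @return list with `z`, `events` (observed events at the analysis) and
#'   `log_hr` (score-based estimate `U/V`; negative favors treatment).
#' @export
logrank_z <- function(trial, at_time) {
  stopifnot(inherits(trial, "sim_trial"))
  .check_number(at_time, "at_time", 0, Inf, TRUE)
  inx <- trial$entry <= at_time
  if (!any(inx)) stop("no patients enrolled by the analysis time")
  fu <- at_time - trial$entry[inx]
  status <- as.integer(trial$time[inx] <= fu)
  time <- pmin(trial$time[inx], fu)
  .logrank_core(time, status, trial$arm[inx])
}

#' Sequential z-trajectory of a simulated trial under a design
#'
#' Each scheduled look is performed at the calendar time its event target
#' `ceiling(t_k * D)` is reached. Looks whose target exceeds the achievable
#' number of events are flagged (`capped`) and evaluated at the time all
#' follow-up is exhausted.
#'
#' @param trial a [simulate_trial()] result.
#' @param design a `gs_design` with a resolved `max_events`.
#' @return an object of class `z_trajectory`: a data frame with one row per
#'   look (`look`, `information_fraction`, `events`, `events_observed`,
#'   `calendar`, `z`, `log_hr_hat`, `capped`).
#' @export
run_looks <- function(trial, design) {
  stopifnot(inherits(trial, "sim_trial"), inherits(design, "gs_design"))
  if (any(is.na(design$events)))
    stop("design has no resolved event targets; build it with 'fixed_D'")
  targets <- design$events
  n_ev <- nrow(trial)                 # no dropout: every patient events
  capped <- targets > n_ev
  cal <- sort(trial$calendar)
  # nudge past the triggering event so it is included despite floating-point
  # noise in entry + time round trips
  tau <- ifelse(capped, cal[n_ev], cal[pmin(targets, n_ev)]) + 1e-9
  res <- lapply(tau, function(tt) logrank_z(trial, tt))
  out <- data.frame(look = seq_along(targets),
                    information_fraction = design$frac,
                    events = targets,
                    events_observed = vapply(res, `[[`, 0, "events"),
                    calendar = tau,
                    z = vapply(res, `[[`, 0, "z"),
                    log_hr_hat = vapply(res, `[[`, 0, "log_hr"),
                    capped = capped)
  class(out) <- c("z_trajectory", "data.frame")
  out
}

#' Apply a design's stopping boundaries to a z-trajectory
#'
#' Scans looks in order: the first futility look with `z` below the futility
#' boundary stops for futility; the first efficacy look with `z` above the
#' efficacy boundary stops for superiority. Non-rejection at the final look
#' is the futility outcome of the trial.
#'
#' @param trajectory a [run_looks()] result (or any data frame with `look`,
#'   `z`, `calendar`).
#' @param design the `gs_design` that produced it.
#' @return list with `stop_look`, `reason` ("futility" or "superiority"),
#'   `stop_time`, `rejected` (logical) and `at_final` (logical).
#' @export
apply_boundaries <- function(trajectory, design) {
  K <- length(design$frac)
  if (nrow(trajectory) != K)
    stop("trajectory and design have different numbers of looks")
  for (k in seq_len(K)) {
    zk <- trajectory$z[k]
    if (design$efficacy[k] && is.finite(design$efficacy_z[k]) &&
        zk > design$efficacy_z[k])
      return(list(stop_look = k, reason = "superiority",
                  stop_time = trajectory$calendar[k], rejected = TRUE,
                  at_final = k == K))
    if (design$futility[k] && is.finite(design$futility_z[k]) &&
        zk < design$futility_z[k])
      return(list(stop_look = k, reason = "futility",
                  stop_time = trajectory$calendar[k], rejected = FALSE,
                  at_final = FALSE))
  }
  list(stop_look = K, reason = "futility",
       stop_time = trajectory$calendar[K], rejected = FALSE, at_final = TRUE)
}

# operating characteristics of one stopped trial
.score_stop <- function(trial, stop_time) {
  assume <- attr(trial, "assumptions")
  inx <- trial$entry <= stop_time
  n_rand <- min(sum(inx), assume$n_total)
  exposure <- sum(pmin(trial$time[inx], stop_time - trial$entry[inx]))
  list(duration = stop_time, n_randomized = n_rand, exposure = exposure)
}

#' Expected event count at a calendar time
#'
#' Deterministic expectation under uniform accrual and Weibull proportional
#' hazards: `sum over arms of n_arm * mean over entry of F_arm(tau - entry)`.
#'
#' @param tau analysis calendar time(s) (months).
#' @param assumptions a [trial_assumptions()].
#' @param log_hr true log hazard ratio (default: the design effect).
#' @param n_quad quadrature points over the accrual window.
#' @return expected events at each `tau`.
#' @export
expected_events_at <- function(tau, assumptions, log_hr = NULL,
                               n_quad = 201L) {
  stopifnot(inherits(assumptions, "trial_assumptions"))
  log_hr <- log_hr %||% log(assumptions$design_hr)
  rho <- assumptions$weibull_shape
  a <- assumptions$accrual_duration
  r <- assumptions$allocation_ratio
  n <- assumptions$n_total
  n_t <- round(n * r / (1 + r)); n_c <- n - n_t
  lam_c <- assumptions$median_control / log(2)^(1 / rho)
  lam_t <- lam_c * exp(-log_hr / rho)
  e <- seq(0, a, length.out = n_quad)
  w <- .simpson_weights(n_quad, e[2] - e[1]) / a
  Fw <- function(u, lam) ifelse(u > 0, 1 - exp(-(u / lam)^rho), 0)
  vapply(tau, function(tt) {
    n_c * sum(w * Fw(tt - e, lam_c)) + n_t * sum(w * Fw(tt - e, lam_t))
  }, 0)
}

#' Expected calendar time to reach a target event count
#'
#' Inverts [expected_events_at()]; returns `Inf` (with a warning) when the
#' target exceeds the number of randomized patients.
#'
#' @param D target event count.
#' @param assumptions a [trial_assumptions()].
#' @param log_hr true log hazard ratio (default: the design effect).
#' @return expected calendar time (months).
#' @export
expected_time_to_events <- function(D, assumptions, log_hr = NULL) {
  stopifnot(inherits(assumptions, "trial_assumptions"))
  .check_number(D, "D", 1, Inf)
  if (D > assumptions$n_total) {
    warning("information cap: target events exceed randomized patients")
    return(Inf)
  }
  hi <- assumptions$accrual_duration + assumptions$median_control
  while (expected_events_at(hi, assumptions, log_hr) < D) hi <- hi * 2
  stats::uniroot(function(tt) expected_events_at(tt, assumptions, log_hr) - D,
                 c(1e-9, hi), tol = 1e-6)$root
}

#' Export a simulated trial or trajectory as CSV
#'
#' @param x a `sim_trial` or `z_trajectory`.
#' @param path file path.
#' @param at_time optional analysis-censoring calendar time for trials; when
#'   supplied, an `event_flag` and censored `time_to_event` are written.
#' @export
export_csv <- function(x, path, at_time = NULL) {
  if (inherits(x, "sim_trial")) {
    df <- data.frame(patient_id = x$id,
                     arm = ifelse(x$arm == 1L, "treated", "control"),
                     entry_time = x$entry, time_to_event = x$time,
                     event_flag = 1L, censor_time = NA_real_)
    if (!is.null(at_time)) {
      fu <- pmax(at_time - x$entry, 0)
      df$event_flag <- as.integer(x$time <= fu)
      df$time_to_event <- pmin(x$time, fu)
      df$censor_time <- at_time
      df <- df[x$entry <= at_time, ]
    }
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else if (inherits(x, "z_trajectory")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  } else stop("don't know how to export objects of class ", class(x)[1])
  invisible(path)
}
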
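#' Historical-cohort summary
#'
#' Per-arm summaries of a historically controlled cohort used to quantify the
#' design-stage uncertainty of the log hazard ratio.
#'
#' @param n_control,n_treated patients per arm.
#' @param median_control,median_treated median survival (months).
#' @param follow_up administrative censoring time (months).
#' @param weibull_shape Weibull shape rho of the survival distribution.
#' @return an object of class `historical_cohort`.
#' @export
historical_cohort <- function(n_control, n_treated, median_control,
                              median_treated, follow_up, weibull_shape = 2) {
  for (nm in c("n_control", "n_treated", "median_control", "median_treated",
               "follow_up", "weibull_shape"))
    .check_number(get(nm), nm, 0, Inf, TRUE)
  structure(list(n_control = n_control, n_treated = n_treated,
                 median_control = median_control,
                 median_treated = median_treated,
                 follow_up = follow_up, weibull_shape = weibull_shape),
            class = "historical_cohort")
}

#' Expected number of events under Weibull survival with fixed follow-up
#'
#' `n * (1 - exp(-(follow_up / lambda)^rho))` with scale
#' `lambda = median / log(2)^(1/rho)`: every patient is observed for the full
#' follow-up window, so the expected event count is n times the Weibull CDF
#' at the censoring time.
#'
#' @param n patients.
#' @param median median survival (months).
#' @param follow_up administrative censoring time (months).
#' @param shape Weibull shape rho.
#' @return expected event count.
#' @export
expected_events_weibull <- function(n, median, follow_up, shape = 2) {
  .check_number(n, "n", 0, Inf, TRUE)
  .check_number(median, "median", 0, Inf, TRUE)
  .check_number(shape, "shape", 0, Inf, TRUE)
  if (!is.numeric(follow_up) || any(follow_up < 0))
    stop("'follow_up' must be nonnegative")
  lambda <- median / log(2)^(1 / shape)
  n * (1 - exp(-(follow_up / lambda)^shape))
}

#' Large-sample standard error of the log hazard ratio from event counts
#'
#' Pooled 1:1 Schoenfeld approximation `2 / sqrt(total_events)`.
#'
#' @param total_events total events across both arms (> 0).
#' @return standard error on the log-HR scale.
#' @export
se_loghr_from_events <- function(total_events) {
  .check_number(total_events, "total_events", 0, Inf, open_lower = TRUE)
  2 / sqrt(total_events)
}

#' Inflate a standard error by a variance multiplier
#'
#' @param se standard error (> 0).
#' @param factor variance multiplier (> 0); the SE is scaled by its square
#'   root.
#' @return inflated standard error.
#' @export
inflate_variance <- function(se, factor) {
  .check_number(se, "se", 0, Inf, TRUE)
  .check_number(factor, "factor", 0, Inf, TRUE)
  se * sqrt(factor)
}

#' Historical success rate
#'
#' @param successes number of successful trials.
#' @param trials number of trials (> 0).
#' @return empirical success probability.
#' @export
success_rate <- function(successes, trials) {
  .check_number(trials, "trials", 1, Inf, integer = TRUE)
  .check_number(successes, "successes", 0, trials, integer = TRUE)
  successes / trials
}

#' Convert an ALSFRS-R point difference to a hazard ratio
#'
#' Each one-point increase on the Revised ALS Functional Rating Scale is
#' assumed to reduce the hazard for death by 11.9%, i.e.
#' `HR = (1 - 0.119)^points`.
#'
#' @param points ALSFRS-R point difference (treated minus control).
#' @param reduction_per_point per-point hazard reduction (default 0.119).
#' @return hazard ratio.
#' @export
alsfrs_to_hr <- function(points, reduction_per_point = 0.119) {
  .check_number(reduction_per_point, "reduction_per_point", 0, 1, FALSE, TRUE)
  (1 - reduction_per_point)^points
}

#' Mixture uncertainty distribution for the log hazard ratio
#'
#' A two-component normal mixture over the log-HR: with probability
#' `p_success` the drug is effective and the log-HR is drawn around the
#' design effect with the (narrow) historical standard error; otherwise it is
#' drawn from a wide component whose variance is inflated to reflect the low
#' historical success rate of the development programme.
#'
#' @param p_success probability that the drug is effective.
#' @param theta_design design log hazard ratio (e.g. `log(0.45)`).
#' @param se_success SE of the log-HR in the effective scenario.
#' @param se_futility SE of the log-HR in the ineffective scenario.
#' @param theta_futility center of the ineffective component; defaults to
#'   `theta_design` (same center, wider spread), may be set to 0 for a
#'   null-centered futility scenario.
#' @return an object of class `mixture_prior`.
#' @export
mixture_prior <- function(p_success, theta_design, se_success, se_futility,
                          theta_futility = theta_design) {
  .check_number(p_success, "p_success", 0, 1)
  .check_number(theta_design, "theta_design")
  .check_number(se_success, "se_success", 0, Inf, TRUE)
  .check_number(se_futility, "se_futility", 0, Inf, TRUE)
  .check_number(theta_futility, "theta_futility")
  structure(list(p_success = p_success, theta_design = theta_design,
                 se_success = se_success, se_futility = se_futility,
                 theta_futility = theta_futility),
            class = "mixture_prior")
}

#' @export
print.mixture_prior <- function(x, ...) {
  cat(sprintf(
    "Mixture prior on log-HR: P(success) = %.3f\n  success:  N(%.4f, %.4f^2)  [HR %.3f]\n  futility: N(%.4f, %.4f^2)\n",
    x$p_success, x$theta_design, x$se_success, exp(x$theta_design),
    x$theta_futility, x$se_futility))
  invisible(x)
}

#' Build the mixture prior from a historical cohort
#'
#' Expected per-arm event counts under Weibull survival are pooled into the
#' large-sample SE of the log-HR (the "success" spread); the "futility"
#' spread inflates that variance (10-fold by default).
#'
#' @param cohort a [historical_cohort()].
#' @param p_success success probability (default 2/28 = 0.071, the historical
#'   phase-3 success rate in ALS).
#' @param design_hr design hazard ratio; defaults to the proportional-hazards
#'   ratio implied by the cohort medians,
#'   `(median_control / median_treated)^rho`.
#' @param variance_inflation variance multiplier for the futility component.
#' @param theta_futility center of the futility component (default: the
#'   design log-HR).
#' @return a [mixture_prior()].
#' @export
prior_from_cohort <- function(cohort, p_success = success_rate(2, 28),
                              design_hr = NULL, variance_inflation = 10,
                              theta_futility = NULL) {
  stopifnot(inherits(cohort, "historical_cohort"))
  ev <- expected_events_weibull(cohort$n_control, cohort$median_control,
                                cohort$follow_up, cohort$weibull_shape) +
        expected_events_weibull(cohort$n_treated, cohort$median_treated,
                                cohort$follow_up, cohort$weibull_shape)
  se <- se_loghr_from_events(ev)
  if (is.null(design_hr))
    design_hr <- (cohort$median_control / cohort$median_treated)^cohort$weibull_shape
  theta <- log(design_hr)
  mixture_prior(p_success = p_success, theta_design = theta,
                se_success = se,
                se_futility = inflate_variance(se, variance_inflation),
                theta_futility = theta_futility %||% theta)
}

#' Sample treatment effects from the mixture prior
#'
#' Draws a Bernoulli success flag and, conditional on it, a log-HR from the
#' corresponding normal component.
#'
#' @param prior a [mixture_prior()].
#' @param n number of draws.
#' @param seed optional integer seed for reproducibility.
#' @return data frame with columns `success` (logical) and `log_hr`.
#' @export
sample_effect <- function(prior, n = 1L, seed = NULL) {
  stopifnot(inherits(prior, "mixture_prior"))
  .check_number(n, "n", 1, Inf, integer = TRUE)
  if (!is.null(seed)) set.seed(seed)
  success <- stats::runif(n) < prior$p_success
  mu <- ifelse(success, prior$theta_design, prior$theta_futility)
  sdv <- ifelse(success, prior$se_success, prior$se_futility)
  data.frame(success = success, log_hr = stats::rnorm(n, mu, sdv))
}

#' Analytic CDF of the mixture prior
#'
#' @param prior a [mixture_prior()].
#' @param q log-HR quantile(s).
#' @return mixture CDF values.
#' @export
mixture_cdf <- function(prior, q) {
  prior$p_success * stats::pnorm(q, prior$theta_design, prior$se_success) +
    (1 - prior$p_success) * stats::pnorm(q, prior$theta_futility,
                                         prior$se_futility)
}
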
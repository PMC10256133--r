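# Run configuration: a JSON document with four blocks (trial, prior, grid,
# run) plus an optional 'placeholders' list naming planning inputs that were
# not available and must be confirmed by the user.

.CONFIG_KEYS <- list(
  top = c("name", "trial", "prior", "grid", "run", "placeholders"),
  trial = c("n_total", "accrual_duration", "median_control", "design_hr",
            "allocation_ratio", "weibull_shape", "alpha", "power", "sided"),
  prior = c("p_success", "design_hr", "se_success", "se_futility",
            "variance_inflation", "theta_futility", "cohort"),
  cohort = c("n_control", "n_treated", "median_control", "median_treated",
             "follow_up", "weibull_shape"),
  grid = c("n_futility_looks", "candidate_fractions", "superiority_fraction",
           "gamma_beta_grid", "gamma_alpha_grid", "max_duration_inflation"),
  run = c("n_replicates", "seed", "output_dir", "criterion"))

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown configuration key%s in '%s': %s",
                 if (length(bad) > 1) "s" else "", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration, rejects unknown keys, fills defaults, and
#' resolves the derived objects (trial assumptions, mixture prior, scheme
#' grid).
#'
#' @param path path to a JSON configuration file.
#' @return an object of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  resolve_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname load_config
#' @param config a raw configuration list (as parsed from JSON).
#' @export
resolve_config <- function(config) {
  .check_keys(config, .CONFIG_KEYS$top, "top level")
  if (is.null(config$trial)) stop("configuration block 'trial' is required")
  .check_keys(config$trial, .CONFIG_KEYS$trial, "trial")
  tr <- config$trial
  assumptions <- trial_assumptions(
    n_total = tr$n_total, accrual_duration = tr$accrual_duration,
    median_control = tr$median_control, design_hr = tr$design_hr,
    allocation_ratio = tr$allocation_ratio %||% 1,
    weibull_shape = tr$weibull_shape %||% 2,
    alpha = tr$alpha %||% 0.025, power = tr$power %||% 0.9,
    sided = as.integer(tr$sided %||% 1L))

  pr <- config$prior %||% list()
  .check_keys(pr, .CONFIG_KEYS$prior, "prior")
  p_success <- pr$p_success %||% success_rate(2, 28)
  .check_number(p_success, "prior.p_success", 0, 1)
  theta_design <- log(pr$design_hr %||% assumptions$design_hr)
  theta_fut <- if (is.null(pr$theta_futility)) theta_design
               else if (identical(pr$theta_futility, "null")) 0
               else as.numeric(pr$theta_futility)
  if (!is.null(pr$cohort)) {
    .check_keys(pr$cohort, .CONFIG_KEYS$cohort, "prior.cohort")
    cohort <- do.call(historical_cohort, pr$cohort)
    prior <- prior_from_cohort(cohort, p_success = p_success,
                               design_hr = exp(theta_design),
                               variance_inflation = pr$variance_inflation %||% 10,
                               theta_futility = theta_fut)
  } else {
    se_s <- pr$se_success
    if (is.null(se_s)) stop("prior needs 'se_success' or a 'cohort' block")
    se_f <- pr$se_futility %||%
      inflate_variance(se_s, pr$variance_inflation %||% 10)
    prior <- mixture_prior(p_success, theta_design, se_s, se_f, theta_fut)
  }

  gr <- config$grid %||% list()
  .check_keys(gr, .CONFIG_KEYS$grid, "grid")
  grid <- scheme_grid(
    n_futility_looks = gr$n_futility_looks %||% c(4L, 5L),
    candidate_fractions = gr$candidate_fractions %||% seq(0.3, 0.9, 0.1),
    superiority_fraction = gr$superiority_fraction %||% 0.6,
    gamma_beta_grid = gr$gamma_beta_grid %||% seq(0.75, 3, 0.25),
    gamma_alpha_grid = gr$gamma_alpha_grid %||% seq(2, 3, 0.25),
    max_duration_inflation = gr$max_duration_inflation %||% 1.10)

  rn <- config$run %||% list()
  .check_keys(rn, .CONFIG_KEYS$run, "run")
  run <- list(n_replicates = as.integer(rn$n_replicates %||% 10000L),
              seed = as.integer(rn$seed %||% 1L),
              output_dir = rn$output_dir %||% ".",
              criterion = match.arg(rn$criterion %||% "duration",
                                    c("duration", "sample_size", "exposure")))

  structure(list(name = config$name %||% "unnamed",
                 trial = tr, assumptions = assumptions, prior = prior,
                 prior_raw = pr, grid = grid, run = run,
                 placeholders = config$placeholders %||% character(0)),
            class = "run_config")
}

#' Serialize a resolved configuration back to JSON
#'
#' The written file reloads to an identical run (round-trip contract).
#'
#' @param config a `run_config`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  raw <- list(name = config$name, trial = config$trial,
              prior = config$prior_raw,
              grid = unclass(config$grid), run = config$run,
              placeholders = config$placeholders)
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run configuration '%s'\n", x$name))
  print(x$assumptions)
  print(x$prior)
  cat(sprintf("  grid: %d timing size(s), %d x %d spending exponents; %d replicates, seed %d, criterion %s\n",
              length(x$grid$n_futility_looks),
              length(x$grid$gamma_alpha_grid), length(x$grid$gamma_beta_grid),
              x$run$n_replicates, x$run$seed, x$run$criterion))
  if (length(x$placeholders))
    cat("  PLACEHOLDER inputs (confirm before use): ",
        paste(x$placeholders, collapse = ", "), "\n")
  invisible(x)
}

#' Built-in fixture configurations
#'
#' Planning configurations emulating the three retrospectively analyzed ALS
#' trials, populated with the published planning quantities (historical
#' cohort medians, standard errors, success rate, Weibull shape). Protocol
#' quantities that were not published (planned sample size, accrual, alpha,
#' power, and for some trials the control median) are shipped as clearly
#' labeled placeholders that the user must replace with the real protocol
#' values; they are listed in the configuration's `placeholders` field.
#' The `toy` fixture is a small configuration for desk-scale runs.
#'
#' @param trial_name one of "dipals", "respistimals", "ceftriaxone", "toy".
#' @return a `run_config`.
#' @export
make_fixture <- function(trial_name = c("dipals", "respistimals",
                                        "ceftriaxone", "toy")) {
  trial_name <- tryCatch(match.arg(trial_name), error = function(e)
    stop("unknown fixture '", trial_name[1],
         "'; valid names: dipals, respistimals, ceftriaxone, toy",
         call. = FALSE))
  pacing_cohort <- list(n_control = 43, n_treated = 43,
                        median_control = 21.4, median_treated = 37.5,
                        follow_up = 24, weibull_shape = 2)
  cfg <- switch(trial_name,
    dipals = list(
      name = "dipals",
      trial = list(n_total = 108, accrual_duration = 24,
                   median_control = 21.4, design_hr = 0.45,
                   allocation_ratio = 1, weibull_shape = 2,
                   alpha = 0.025, power = 0.9, sided = 1L),
      prior = list(p_success = success_rate(2, 28), cohort = pacing_cohort,
                   variance_inflation = 10),
      run = list(n_replicates = 10000L, seed = 1L, criterion = "duration"),
      placeholders = c("trial.n_total", "trial.accrual_duration",
                       "trial.alpha", "trial.power")),
    respistimals = list(
      name = "respistimals",
      trial = list(n_total = 74, accrual_duration = 18,
                   median_control = 21.4, design_hr = 0.45,
                   allocation_ratio = 1, weibull_shape = 2,
                   alpha = 0.025, power = 0.9, sided = 1L),
      prior = list(p_success = success_rate(2, 28), cohort = pacing_cohort,
                   variance_inflation = 10),
      run = list(n_replicates = 10000L, seed = 1L, criterion = "duration"),
      placeholders = c("trial.n_total", "trial.accrual_duration",
                       "trial.median_control", "trial.design_hr",
                       "trial.alpha", "trial.power")),
    ceftriaxone = list(
      name = "ceftriaxone",
      trial = list(n_total = 500, accrual_duration = 36,
                   median_control = 28.9,
                   design_hr = (28.9 / 43.4)^2,
                   allocation_ratio = 1, weibull_shape = 2,
                   alpha = 0.025, power = 0.9, sided = 1L),
      prior = list(p_success = success_rate(2, 28), se_success = 0.147,
                   variance_inflation = 10),
      run = list(n_replicates = 10000L, seed = 1L, criterion = "duration"),
      placeholders = c("trial.n_total", "trial.accrual_duration",
                       "trial.alpha", "trial.power")),
    toy = list(
      name = "toy",
      trial = list(n_total = 120, accrual_duration = 24,
                   median_control = 21.4, design_hr = 0.45,
                   allocation_ratio = 1, weibull_shape = 2,
                   alpha = 0.025, power = 0.9, sided = 1L),
      prior = list(p_success = success_rate(2, 28), cohort = pacing_cohort,
                   variance_inflation = 10),
      grid = list(n_futility_looks = 4L,
                  candidate_fractions = c(0.3, 0.4, 0.5, 0.6, 0.7),
                  superiority_fraction = 0.6,
                  gamma_beta_grid = c(2, 2.5, 3),
                  gamma_alpha_grid = 2.5),
      run = list(n_replicates = 500L, seed = 1L, criterion = "duration"),
      placeholders = character(0)))
  resolve_config(cfg)
}
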
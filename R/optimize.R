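#' End-to-end scheme optimization for a configuration
#'
#' Runs the full pipeline: enumerate the candidate schemes, build each
#' group-sequential design (boundaries and inflated event target), apply the
#' maximum-duration exclusion, evaluate every scheme over trials simulated
#' from the mixture prior with common random numbers, and select the optimum
#' under the configured criterion.
#'
#' @param config a `run_config` (see [load_config()], [make_fixture()]).
#' @param n_replicates optional override of the configured replicate count.
#' @param verbose log grid size, exclusion count and replicate count.
#' @return list with `schemes` (the annotated `scheme_set`), `evaluations`,
#'   `selection` (see [select_optimal()]), and the reference `fixed` and
#'   `conventional` designs evaluated on the same replicates.
#' @export
optimize_schemes <- function(config, n_replicates = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  assume <- config$assumptions
  spec <- spending_spec(assume$alpha, 1 - assume$power,
                        sided = assume$sided)
  fixed_D <- .fixed_events(assume)
  schemes <- enumerate_schemes(config$grid, spec, fixed_D = fixed_D)
  schemes <- apply_duration_exclusion(schemes, assume,
                                      config$grid$max_duration_inflation)
  n_rep <- n_replicates %||% config$run$n_replicates
  if (verbose)
    message(sprintf(
      "optimize: %d candidate schemes, %d excluded (max duration), %d replicates, seed %d",
      nrow(schemes), sum(schemes$excluded), n_rep, config$run$seed))
  ev <- evaluate_schemes(schemes, config$prior, assume,
                         n_replicates = n_rep, seed = config$run$seed)
  sel <- select_optimal(ev, config$run$criterion)

  refs <- list(fixed = fixed_design(assume),
               conventional = conventional_design(assume))
  ev_ref <- evaluate_schemes(refs, config$prior, assume,
                             n_replicates = n_rep, seed = config$run$seed)
  ev_ref$summary$scheme <- names(refs)
  list(schemes = schemes, evaluations = ev, selection = sel,
       references = ev_ref, fixed_D = fixed_D)
}

#' Operating characteristics across a grid of true hazard ratios
#'
#' Re-simulates the trial under each fixed hazard ratio (enrollment, control
#' survival and allocation held at their configured values) and scores the
#' optimized, conventional single-look and no-interim designs on the same
#' replicates, reproducing the treatment-effect sweep used to profile an
#' optimized scheme from very beneficial to very harmful effects.
#'
#' @param config a `run_config`.
#' @param hr_grid hazard ratios to sweep.
#' @param optimal_design the optimized `gs_design` (from
#'   [optimize_schemes()]); if `NULL`, the configuration is optimized first.
#' @param n_replicates replicates per scenario (configured count by
#'   default).
#' @return data frame with one row per (hazard ratio, design): mean/median
#'   duration, mean sample size, mean exposure, rejection and early-stop
#'   probabilities.
#' @export
scenario_sweep <- function(config, hr_grid, optimal_design = NULL,
                           n_replicates = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!length(hr_grid) || any(hr_grid <= 0))
    stop("'hr_grid' must be a nonempty vector of positive hazard ratios")
  assume <- config$assumptions
  if (is.null(optimal_design))
    optimal_design <- optimize_schemes(config, n_replicates,
                                       verbose = FALSE)$selection$design
  designs <- list(optimized = optimal_design,
                  conventional = conventional_design(assume),
                  no_interim = fixed_design(assume))
  n_rep <- n_replicates %||% config$run$n_replicates
  out <- lapply(hr_grid, function(hr) {
    ev <- evaluate_schemes(designs, prior = NULL, assumptions = assume,
                           n_replicates = n_rep, seed = config$run$seed,
                           fixed_log_hr = log(hr))
    s <- ev$summary
    early <- vapply(seq_along(designs), function(i) {
      sp <- ev$stop_probs[ev$stop_probs$scheme == i, ]
      K <- length(designs[[i]]$frac)
      sum(sp$probability[sp$look < K])
    }, 0)
    data.frame(hr = hr, design = names(designs),
               mean_duration = s$mean_duration,
               median_duration = s$median_duration,
               mean_n = s$mean_n, mean_exposure = s$mean_exposure,
               p_reject = s$p_reject, p_stop_early = early)
  })
  do.call(rbind, out)
}
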
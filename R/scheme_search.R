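#' Candidate scheme grid
#'
#' The search space of interim-analysis schemes: sets of 4 or 5 futility
#' looks drawn from candidate information fractions (every set must contain
#' the fixed superiority look), crossed with grids of alpha- and beta-spending
#' exponents.
#'
#' @param n_futility_looks allowed numbers of futility analyses.
#' @param candidate_fractions candidate look fractions.
#' @param superiority_fraction the fixed superiority look (must be a
#'   candidate fraction).
#' @param gamma_beta_grid beta-spending exponents (Pocock-type 0.75 to
#'   O'Brien-Fleming-type 3.00 by default).
#' @param gamma_alpha_grid alpha-spending exponents (2.00 to 3.00 by
#'   default).
#' @param max_duration_inflation exclusion threshold: schemes whose expected
#'   maximum trial duration exceeds this multiple of the no-interim design's
#'   duration are excluded.
#' @return an object of class `scheme_grid`.
#' @export
scheme_grid <- function(n_futility_looks = c(4L, 5L),
                        candidate_fractions = seq(0.3, 0.9, by = 0.1),
                        superiority_fraction = 0.6,
                        gamma_beta_grid = seq(0.75, 3, by = 0.25),
                        gamma_alpha_grid = seq(2, 3, by = 0.25),
                        max_duration_inflation = 1.10) {
  candidate_fractions <- round(sort(unique(candidate_fractions)), 10)
  if (any(candidate_fractions <= 0) || any(candidate_fractions >= 1))
    stop("candidate fractions must lie in (0, 1)")
  if (!any(abs(candidate_fractions - superiority_fraction) < 1e-9))
    stop("superiority_fraction must be one of the candidate fractions")
  if (!length(gamma_beta_grid) || !length(gamma_alpha_grid) ||
      !length(n_futility_looks))
    stop("scheme grid must be nonempty")
  structure(list(n_futility_looks = as.integer(n_futility_looks),
                 candidate_fractions = candidate_fractions,
                 superiority_fraction = superiority_fraction,
                 gamma_beta_grid = gamma_beta_grid,
                 gamma_alpha_grid = gamma_alpha_grid,
                 max_duration_inflation = max_duration_inflation),
            class = "scheme_grid")
}

#' Enumerate candidate interim-analysis schemes
#'
#' All futility-look subsets of the allowed sizes containing the superiority
#' look, crossed with both spending-exponent grids. Enumeration is
#' deterministic, duplicate-free and stably ordered (timing sets in
#' lexicographic order, then gamma_beta, then gamma_alpha).
#'
#' @param grid a [scheme_grid()].
#' @param spec a base [spending_spec()] supplying alpha, beta and sidedness;
#'   its exponents are replaced by each grid point.
#' @param fixed_D optional fixed-design event count; when supplied, full
#'   `gs_design` objects (with inflated event targets) are attached.
#' @return a data frame of class `scheme_set` with one row per scheme
#'   (columns `scheme`, `timing` label, `gamma_alpha`, `gamma_beta` and a
#'   `fractions` list column); when `fixed_D` is given, a `designs` attribute
#'   holds the corresponding list of `gs_design` objects.
#' @export
enumerate_schemes <- function(grid, spec, fixed_D = NULL) {
  stopifnot(inherits(grid, "scheme_grid"), inherits(spec, "spending_spec"))
  cand <- grid$candidate_fractions
  sup <- grid$superiority_fraction
  others <- cand[abs(cand - sup) >= 1e-9]
  sets <- list()
  for (nf in sort(grid$n_futility_looks)) {
    if (nf - 1L > length(others))
      stop("not enough candidate fractions for ", nf, " futility looks")
    cmb <- if (nf - 1L == 0L) matrix(numeric(0), ncol = 0, nrow = 1)
           else t(utils::combn(others, nf - 1L))
    sets <- c(sets, lapply(seq_len(nrow(cmb)),
                           function(i) sort(c(cmb[i, ], sup))))
  }
  sets <- sets[order(vapply(sets, length, 0L),
                     vapply(sets, paste, "", collapse = ","))]
  tab <- expand.grid(set_id = seq_along(sets),
                     gamma_beta = grid$gamma_beta_grid,
                     gamma_alpha = grid$gamma_alpha_grid,
                     KEEP.OUT.ATTRS = FALSE)
  tab <- tab[order(tab$set_id, tab$gamma_beta, tab$gamma_alpha), ]
  fractions <- sets[tab$set_id]
  out <- data.frame(scheme = seq_len(nrow(tab)),
                    timing = vapply(fractions, paste, "", collapse = "/"),
                    gamma_alpha = tab$gamma_alpha,
                    gamma_beta = tab$gamma_beta)
  out$fractions <- fractions
  attr(out, "superiority_fraction") <- sup
  attr(out, "spec") <- spec
  if (!is.null(fixed_D)) {
    attr(out, "designs") <- lapply(seq_len(nrow(out)), function(i)
      .scheme_design(out, i, fixed_D))
    attr(out, "fixed_D") <- fixed_D
  }
  class(out) <- c("scheme_set", "data.frame")
  out
}

.scheme_design <- function(schemes, i, fixed_D) {
  spec <- attr(schemes, "spec")
  sp <- spending_spec(spec$alpha_total, spec$beta_total,
                      gamma_alpha = schemes$gamma_alpha[i],
                      gamma_beta = schemes$gamma_beta[i],
                      futility_binding = spec$futility_binding,
                      sided = spec$sided)
  sch <- look_schedule(schemes$fractions[[i]],
                       attr(schemes, "superiority_fraction"))
  compute_boundaries(sch, sp, fixed_D = fixed_D)
}

#' The no-interim (fixed) reference design
#'
#' A single analysis at full information with the fixed-design event count.
#'
#' @param assumptions a [trial_assumptions()].
#' @return a `gs_design`.
#' @export
fixed_design <- function(assumptions) {
  sp <- spending_spec(assumptions$alpha, 1 - assumptions$power,
                      sided = assumptions$sided)
  compute_boundaries(look_schedule(1), sp,
                     fixed_D = .fixed_events(assumptions))
}

#' A conventional single-interim reference design
#'
#' One interim analysis at 60% of the maximum events with
#' O'Brien-Fleming-type (power-family exponent 3) efficacy and nonbinding
#' futility rules; reflects commonly used interim design settings.
#'
#' @param assumptions a [trial_assumptions()].
#' @param fraction interim-look information fraction (default 0.6).
#' @param gamma spending exponent for both families (default 3).
#' @return a `gs_design`.
#' @export
conventional_design <- function(assumptions, fraction = 0.6, gamma = 3) {
  sp <- spending_spec(assumptions$alpha, 1 - assumptions$power,
                      gamma_alpha = gamma, gamma_beta = gamma,
                      sided = assumptions$sided)
  compute_boundaries(look_schedule(c(fraction, 1), fraction), sp,
                     fixed_D = .fixed_events(assumptions))
}

#' Exclude schemes by maximum trial duration
#'
#' A scheme's maximum trial duration is the expected calendar time to reach
#' its inflated maximum event count under the design assumptions; schemes
#' exceeding `max_duration_inflation` times the no-interim design's duration
#' are flagged as excluded.
#'
#' @param schemes a `scheme_set` built with `fixed_D` (designs attached).
#' @param assumptions a [trial_assumptions()].
#' @param max_duration_inflation threshold multiple (default 1.10).
#' @return the `scheme_set` with columns `max_events`, `max_duration`,
#'   `excluded` and `exclusion_reason` added; attribute
#'   `fixed_design_duration` carries the reference duration.
#' @export
apply_duration_exclusion <- function(schemes, assumptions,
                                     max_duration_inflation = 1.10) {
  stopifnot(inherits(schemes, "scheme_set"))
  designs <- attr(schemes, "designs")
  if (is.null(designs))
    stop("schemes carry no designs; enumerate with 'fixed_D'")
  fd <- .fixed_events(assumptions)
  dur_fixed <- expected_time_to_events(fd, assumptions)
  limit <- max_duration_inflation * dur_fixed
  schemes$max_events <- vapply(designs, `[[`, 0L, "max_events")
  schemes$max_duration <- vapply(schemes$max_events, function(D) {
    if (D > assumptions$n_total) Inf
    else expected_time_to_events(D, assumptions)
  }, 0)
  schemes$excluded <- schemes$max_duration > limit
  schemes$exclusion_reason <- ifelse(
    schemes$excluded,
    sprintf("max duration %.1f > %.2f x fixed-design %.1f months",
            schemes$max_duration, max_duration_inflation, dur_fixed), "")
  attr(schemes, "fixed_design_duration") <- dur_fixed
  schemes
}

#' Evaluate schemes over simulated trials drawn from the mixture prior
#'
#' For each replicate, one treatment effect is drawn from the prior (or the
#' fixed `log_hr` is used), one trial is simulated, and every design is
#' scored on that same trial (common random numbers), so scheme differences
#' are not confounded by simulation noise. The sequential log-rank statistic
#' is cached per distinct event target within a replicate.
#'
#' @param schemes a `scheme_set` with designs attached, or a plain list of
#'   `gs_design` objects.
#' @param prior a [mixture_prior()], or `NULL` when `fixed_log_hr` is given.
#' @param assumptions a [trial_assumptions()].
#' @param n_replicates number of simulated trials (the planning default is
#'   10,000; reduce for desk-scale runs).
#' @param seed base seed; each replicate uses an index-derived stream so the
#'   evaluation is independent of scheme order and replicate order.
#' @param fixed_log_hr optional fixed true effect overriding the prior.
#' @return an object of class `scheme_evaluations`: list with `summary` (one
#'   row per scheme: mean/median duration, mean sample size, mean exposure,
#'   power under the success component, overall rejection rate), `stop_probs`
#'   (long data frame of per-look stopping probabilities by reason) and the
#'   evaluated `designs`.
#' @export
evaluate_schemes <- function(schemes, prior, assumptions,
                             n_replicates = 10000L, seed = 1L,
                             fixed_log_hr = NULL) {
  designs <- if (inherits(schemes, "scheme_set")) attr(schemes, "designs")
             else schemes
  if (is.null(designs) || !length(designs))
    stop("no designs to evaluate")
  .check_number(n_replicates, "n_replicates", 1, Inf, integer = TRUE)
  S <- length(designs)
  ids <- if (inherits(schemes, "scheme_set")) schemes$scheme else seq_len(S)
  K_s <- vapply(designs, function(d) length(d$frac), 0L)
  all_targets <- sort(unique(unlist(lapply(designs, `[[`, "events"))))

  dur <- nrand <- expo <- matrix(NA_real_, n_replicates, S)
  rejected <- matrix(FALSE, n_replicates, S)
  stoplook <- matrix(NA_integer_, n_replicates, S)
  reason_fut <- matrix(FALSE, n_replicates, S)
  success <- logical(n_replicates)
  drawn_loghr <- numeric(n_replicates)

  for (i in seq_len(n_replicates)) {
    set.seed(.replicate_seed(seed, i))
    if (is.null(fixed_log_hr)) {
      eff <- sample_effect(prior, 1L)
      success[i] <- eff$success; drawn_loghr[i] <- eff$log_hr
    } else {
      success[i] <- TRUE; drawn_loghr[i] <- fixed_log_hr
    }
    trial <- simulate_trial(assumptions, drawn_loghr[i])
    n_ev <- nrow(trial)
    cal <- sort(trial$calendar)
    zc <- new.env(parent = emptyenv())
    zfun <- function(d) {
      key <- as.character(min(d, n_ev))
      if (is.null(zc[[key]])) {
        tau <- cal[min(d, n_ev)] + 1e-9
        lr <- logrank_z(trial, tau)
        zc[[key]] <- list(z = lr$z, tau = tau)
      }
      zc[[key]]
    }
    for (s in seq_len(S)) {
      de <- designs[[s]]
      res <- lapply(de$events, zfun)
      traj <- data.frame(look = seq_len(K_s[s]),
                         z = vapply(res, `[[`, 0, "z"),
                         calendar = vapply(res, `[[`, 0, "tau"))
      dec <- apply_boundaries(traj, de)
      sc <- .score_stop(trial, dec$stop_time)
      dur[i, s] <- sc$duration; nrand[i, s] <- sc$n_randomized
      expo[i, s] <- sc$exposure
      rejected[i, s] <- dec$rejected
      stoplook[i, s] <- dec$stop_look
      reason_fut[i, s] <- !dec$rejected
    }
  }

  summary <- data.frame(
    scheme = ids,
    mean_duration = colMeans(dur),
    median_duration = apply(dur, 2, stats::median),
    mean_n = colMeans(nrand),
    mean_exposure = colMeans(expo),
    p_reject = colMeans(rejected),
    power_success = vapply(seq_len(S), function(s)
      if (any(success)) mean(rejected[success, s]) else NA_real_, 0),
    n_looks = K_s)
  if (inherits(schemes, "scheme_set")) {
    summary$timing <- schemes$timing
    summary$gamma_alpha <- schemes$gamma_alpha
    summary$gamma_beta <- schemes$gamma_beta
    if (!is.null(schemes$excluded)) {
      summary$excluded <- schemes$excluded
      summary$exclusion_reason <- schemes$exclusion_reason
    }
  }
  if (is.null(summary$excluded)) {
    summary$excluded <- FALSE
    summary$exclusion_reason <- ""
  }

  sp <- do.call(rbind, lapply(seq_len(S), function(s) {
    tb <- table(factor(stoplook[, s], levels = seq_len(K_s[s])),
                factor(ifelse(reason_fut[, s], "futility", "superiority"),
                       levels = c("futility", "superiority")))
    data.frame(scheme = ids[s],
               look = rep(seq_len(K_s[s]), 2),
               information_fraction = rep(designs[[s]]$frac, 2),
               reason = rep(c("futility", "superiority"), each = K_s[s]),
               probability = c(tb[, "futility"], tb[, "superiority"]) /
                 n_replicates)
  }))

  structure(list(summary = summary, stop_probs = sp, designs = designs,
                 n_replicates = n_replicates, seed = seed,
                 p_success_draws = mean(success)),
            class = "scheme_evaluations")
}

#' @export
print.scheme_evaluations <- function(x, ...) {
  cat(sprintf("Scheme evaluations: %d schemes x %d replicates (seed %d)\n",
              nrow(x$summary), x$n_replicates, x$seed))
  print(utils::head(x$summary[order(x$summary$mean_duration),
                              setdiff(names(x$summary), "exclusion_reason")],
                    10), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Rank evaluated schemes and select the optimum
#'
#' Minimizes the mean of the chosen criterion over non-excluded schemes.
#' Ties break deterministically: smaller mean sample size, then fewer looks,
#' then lexicographic timing.
#'
#' @param evaluations a [evaluate_schemes()] result.
#' @param criterion "duration", "sample_size" or "exposure".
#' @return list with `optimum` (the winning summary row), `design` (its
#'   `gs_design`), and `ranking` (all schemes, best first, excluded last).
#' @export
select_optimal <- function(evaluations,
                           criterion = c("duration", "sample_size",
                                         "exposure")) {
  stopifnot(inherits(evaluations, "scheme_evaluations"))
  criterion <- match.arg(criterion)
  col <- switch(criterion, duration = "mean_duration",
                sample_size = "mean_n", exposure = "mean_exposure")
  s <- evaluations$summary
  if (all(s$excluded)) stop("all schemes were excluded; exclusion reasons:\n",
                            paste(unique(s$exclusion_reason), collapse = "\n"))
  ord <- order(s$excluded, s[[col]], s$mean_n, s$n_looks,
               if (!is.null(s$timing)) s$timing else s$scheme)
  ranking <- s[ord, ]
  ranking$rank <- seq_len(nrow(ranking))
  opt <- ranking[1, ]
  list(optimum = opt,
       design = evaluations$designs[[match(opt$scheme, s$scheme)]],
       ranking = ranking, criterion = criterion)
}
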
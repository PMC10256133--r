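#' An observed interim-analysis summary
#'
#' A per-look summary as published: either a hazard ratio with its 95%
#' confidence interval, or a z-statistic with an event count. The z and
#' implied event count are reconstructed from the CI when needed.
#'
#' @param hr hazard ratio point estimate.
#' @param lo,hi 95% CI bounds (`0 < lo < hr < hi`).
#' @param z z-statistic (alternative to the CI; positive favors treatment).
#' @param events event count at the look.
#' @param information_fraction optional information fraction of the look
#'   within its design (events / maximum planned events).
#' @param calendar_time optional calendar time (months).
#' @return an object of class `observed_look`.
#' @export
observed_look <- function(hr = NULL, lo = NULL, hi = NULL, z = NULL,
                          events = NULL, information_fraction = NULL,
                          calendar_time = NULL) {
  if (!is.null(hr)) {
    rec <- z_from_hr_ci(hr, lo, hi)
    z <- z %||% rec$z
    events <- events %||% rec$events
  } else if (is.null(z)) {
    stop("supply either (hr, lo, hi) or (z, events)")
  }
  structure(list(hr = hr, lo = lo, hi = hi, z = z, events = events,
                 information_fraction = information_fraction,
                 calendar_time = calendar_time),
            class = "observed_look")
}

#' Reconstruct a z-statistic and event count from an HR and its 95% CI
#'
#' Assumes a Wald interval on the log-HR: `SE = log(hi/lo) / (2 * 1.96)`,
#' `z = -log(hr) / SE` (positive favors treatment) and an implied event
#' count `4 / SE^2` from the pooled large-sample approximation.
#'
#' @param hr hazard ratio point estimate.
#' @param lo,hi confidence bounds.
#' @param conf_z normal quantile of the interval (default `qnorm(0.975)`).
#' @return list with `z`, `se` and `events` (implied, real-valued).
#' @export
z_from_hr_ci <- function(hr, lo, hi, conf_z = stats::qnorm(0.975)) {
  .check_number(hr, "hr", 0, Inf, TRUE)
  .check_number(lo, "lo", 0, Inf, TRUE)
  .check_number(hi, "hi", 0, Inf, TRUE)
  if (!(lo < hr && hr < hi))
    stop("confidence interval must satisfy 0 < lo < hr < hi")
  se <- log(hi / lo) / (2 * conf_z)
  list(z = -log(hr) / se, se = se, events = 4 / se^2)
}

#' Apply a design's boundaries retrospectively to observed looks
#'
#' Observed looks are aligned to the design's looks either by their supplied
#' information fractions (nearest design look; a mismatch beyond
#' `tolerance` is an error) or, when no fractions are supplied, by order.
#' Boundaries are then scanned in sequence: the first futility look with z
#' below its futility boundary stops for futility; the first efficacy look
#' with z above its efficacy boundary stops for superiority; otherwise the
#' decision is to continue (or, at the final look, the trial fails).
#'
#' @param looks a list of [observed_look()]s (a single look is promoted), or
#'   a data frame with columns `hr, lo, hi` and/or `z`, plus optionally
#'   `events`, `information_fraction`, `calendar_time`.
#' @param design a `gs_design`.
#' @param align "auto" (fractions if available, else order), "fraction" or
#'   "order".
#' @param tolerance maximum |observed - design| information-fraction
#'   mismatch for fraction alignment.
#' @return an object of class `monitor_decision`: list with `stop_look`
#'   (design look index or `NA`), `reason` ("futility", "superiority" or
#'   "continue"), `boundary` values at the decision look, and the aligned
#'   per-look `table`.
#' @export
monitor_trajectory <- function(looks, design,
                               align = c("auto", "fraction", "order"),
                               tolerance = 0.05) {
  stopifnot(inherits(design, "gs_design"))
  align <- match.arg(align)
  if (inherits(looks, "observed_look")) looks <- list(looks)
  if (is.data.frame(looks)) {
    looks <- lapply(seq_len(nrow(looks)), function(i) {
      r <- as.list(looks[i, , drop = FALSE])
      r <- r[!vapply(r, function(v) is.null(v) || all(is.na(v)), TRUE)]
      do.call(observed_look, r)
    })
  }
  n <- length(looks)
  if (n == 0L) stop("no observed looks supplied")
  if (n > length(design$frac))
    stop("more observed looks than design looks")
  fracs <- vapply(looks, function(l) l$information_fraction %||% NA_real_, 0)
  use_frac <- switch(align, auto = all(!is.na(fracs)), fraction = TRUE,
                     order = FALSE)
  if (use_frac) {
    if (any(is.na(fracs)))
      stop("fraction alignment requested but some looks lack an information fraction")
    idx <- vapply(fracs, function(f) which.min(abs(design$frac - f)), 0L)
    err <- abs(design$frac[idx] - fracs)
    if (any(err > tolerance))
      stop("unalignable trajectory: observed fractions ",
           paste(sprintf("%.3f", fracs[err > tolerance]), collapse = ", "),
           " are more than ", tolerance, " from any design look (design: ",
           paste(sprintf("%.3f", design$frac), collapse = ", "), ")")
    if (anyDuplicated(idx))
      stop("unalignable trajectory: two observed looks map to one design look")
  } else {
    idx <- seq_len(n)
    implied <- vapply(looks, function(l) {
      if (!is.null(l$events) && !is.na(design$max_events))
        l$events / design$max_events else NA_real_
    }, 0)
    message("aligning observed looks by order; implied fractions: ",
            paste(ifelse(is.na(implied), "?", sprintf("%.2f", implied)),
                  collapse = ", "))
  }
  tab <- data.frame(observed = seq_len(n), look = idx,
                    information_fraction = design$frac[idx],
                    z = vapply(looks, `[[`, 0, "z"),
                    futility_z = design$futility_z[idx],
                    efficacy_z = design$efficacy_z[idx])
  decision <- list(stop_look = NA_integer_, reason = "continue",
                   boundary = NULL, table = tab)
  for (i in seq_len(n)) {
    k <- idx[i]; zk <- tab$z[i]
    if (design$efficacy[k] && is.finite(design$efficacy_z[k]) &&
        zk > design$efficacy_z[k]) {
      decision$stop_look <- k; decision$reason <- "superiority"
      decision$boundary <- list(efficacy_z = design$efficacy_z[k],
                                futility_z = design$futility_z[k])
      break
    }
    if (design$futility[k] && is.finite(design$futility_z[k]) &&
        zk < design$futility_z[k]) {
      decision$stop_look <- k; decision$reason <- "futility"
      decision$boundary <- list(efficacy_z = design$efficacy_z[k],
                                futility_z = design$futility_z[k])
      break
    }
  }
  class(decision) <- "monitor_decision"
  decision
}

#' @export
print.monitor_decision <- function(x, ...) {
  if (x$reason == "continue") {
    cat("Decision: continue (no boundary crossed)\n")
  } else {
    cat(sprintf("Decision: stop for %s at look %d (futility bound %.3f, efficacy bound %s)\n",
                x$reason, x$stop_look,
                x$boundary$futility_z %||% NA_real_,
                ifelse(is.finite(x$boundary$efficacy_z %||% NA_real_),
                       sprintf("%.3f", x$boundary$efficacy_z), "-")))
  }
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Conditional power at an interim analysis
#'
#' Probability that the final analysis rejects, given the current statistic
#' and an assumed hazard ratio for the remaining data, via the B-value
#' decomposition: with `B(t) = z sqrt(t)`, the final `z(1) = B(1)` is normal
#' with mean `B(t) + drift * (1 - t)` and variance `1 - t`, so
#' `CP = Phi((z sqrt(t) + drift (1 - t) - u_final) / sqrt(1 - t))` with
#' `u_final` the final efficacy boundary.
#'
#' @param z_current observed z (positive favors treatment).
#' @param info_fraction current information fraction, in (0, 1).
#' @param assumed_hr hazard ratio assumed for the remaining data.
#' @param design a `gs_design` supplying the final boundary and, if
#'   resolved, the maximum event count for the drift.
#' @param drift optional explicit drift at full information, overriding
#'   `assumed_hr`; required if the design has no resolved `max_events`.
#' @param allocation_ratio treated:control ratio used for the drift.
#' @return conditional power in \[0, 1\].
#' @export
conditional_power <- function(z_current, info_fraction, assumed_hr = NULL,
                              design = NULL, drift = NULL,
                              allocation_ratio = 1) {
  .check_number(z_current, "z_current")
  .check_number(info_fraction, "info_fraction", 0, 1, TRUE, TRUE)
  if (is.null(drift)) {
    if (is.null(assumed_hr) || is.null(design) || is.na(design$max_events))
      stop("supply 'drift' or ('assumed_hr' and a design with max_events)")
    drift <- .drift_at(log(assumed_hr), design$max_events, allocation_ratio)
  }
  u_final <- if (!is.null(design)) {
    design$efficacy_z[length(design$efficacy_z)]
  } else stats::qnorm(0.975)
  t <- info_fraction
  stats::pnorm((z_current * sqrt(t) + drift * (1 - t) - u_final) /
               sqrt(1 - t))
}
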
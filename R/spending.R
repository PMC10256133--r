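#' Power-family error-spending specification
#'
#' Bundles the total one-sided type-I error, the type-II error, and the two
#' Kim-DeMets power-family exponents that control how fast each error budget
#' is spent over the information scale. Exponents near 0.75 spend error early
#' (Pocock-type boundaries); exponents near 3 spend it late
#' (O'Brien-Fleming-type).
#'
#' @param alpha_total total type-I error (one-sided by default).
#' @param beta_total total type-II error (1 - power).
#' @param gamma_alpha power-family exponent for efficacy (alpha) spending.
#' @param gamma_beta power-family exponent for futility (beta) spending.
#' @param futility_binding logical; futility boundaries are nonbinding by
#'   default (alpha control never relies on futility stopping).
#' @param sided 1 (upper one-sided test, the default) or 2 (symmetric
#'   two-sided; the upper boundary then spends `alpha_total / 2`).
#' @return an object of class `spending_spec`.
#' @export
spending_spec <- function(alpha_total = 0.025, beta_total = 0.1,
                          gamma_alpha = 2.5, gamma_beta = 2.5,
                          futility_binding = FALSE, sided = 1L) {
  .check_number(alpha_total, "alpha_total", 0, 1, TRUE, TRUE)
  .check_number(beta_total, "beta_total", 0, 1, TRUE, TRUE)
  .check_number(gamma_alpha, "gamma_alpha", 0, Inf, TRUE)
  .check_number(gamma_beta, "gamma_beta", 0, Inf, TRUE)
  if (!sided %in% c(1L, 2L)) stop("'sided' must be 1 or 2")
  structure(list(alpha_total = alpha_total, beta_total = beta_total,
                 gamma_alpha = gamma_alpha, gamma_beta = gamma_beta,
                 futility_binding = isTRUE(futility_binding),
                 sided = as.integer(sided)),
            class = "spending_spec")
}

#' Interim-analysis look schedule
#'
#' Looks are placed at fractions of the maximum planned event count. Every
#' non-final look tests futility; superiority is tested at
#' `superiority_fraction` (if present among the looks) and at the final
#' analysis. A final look at fraction 1 is appended if absent.
#'
#' @param information_fractions strictly increasing fractions in (0, 1].
#' @param superiority_fraction interim look at which efficacy is also tested
#'   (default 0.6; ignored if not among the information fractions).
#' @return an object of class `look_schedule` with elements `frac`,
#'   `efficacy` and `futility` (logical masks per look).
#' @export
look_schedule <- function(information_fractions, superiority_fraction = 0.6) {
  frac <- sort(unique(as.numeric(information_fractions)))
  if (length(frac) == 0L || any(frac <= 0) || any(frac > 1))
    stop("information fractions must lie in (0, 1]")
  if (max(frac) < 1) frac <- c(frac, 1)
  K <- length(frac)
  futility <- seq_len(K) < K
  efficacy <- abs(frac - superiority_fraction) < 1e-9 | seq_len(K) == K
  structure(list(frac = frac, efficacy = efficacy, futility = futility,
                 superiority_fraction = superiority_fraction),
            class = "look_schedule")
}

#' Cumulative error spent by the power family
#'
#' `f(t) = total * t^gamma`: nondecreasing in the information fraction `t`,
#' zero at `t = 0` and exhausting the budget at `t = 1`.
#'
#' @param t information fraction(s) in \[0, 1\].
#' @param gamma power-family exponent (> 0).
#' @param total total error budget.
#' @return cumulative error spent at `t`.
#' @export
power_spending <- function(t, gamma, total) {
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1))
    stop("information fraction 't' must lie in [0, 1]")
  .check_number(gamma, "gamma", 0, Inf, TRUE)
  total * t^gamma
}

# ---- recursive integration over the sequential z-process --------------------
#
# The canonical joint law: z_k at information fractions t_k with
# cov(z_j, z_k) = sqrt(t_j / t_k), equivalently the B-value s_k = z_k sqrt(t_k)
# has independent increments  s_k - s_{k-1} ~ N(drift * (t_k - t_{k-1}),
# t_k - t_{k-1}).  The continuation density is propagated on a Simpson grid in
# s-space; boundaries are solved look by look so that incremental crossing
# probabilities equal the prescribed spending increments.

.simpson_weights <- function(n, h) {
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  w * h / 3
}

.GS_TRUNC <- 8.5   # +- sd units retained around the increment mean

# Sequential solve/propagate over one set of looks.
# frac: information fractions; drift: mean of z at t = 1.
# up_fixed / lo_fixed: z-scale boundaries (Inf / -Inf when absent);
# up_target / lo_target: incremental crossing probabilities to be matched
# (NA where the boundary is fixed or absent). Solved bounds override fixed.
.gs_pass <- function(frac, drift, up_fixed = NULL, lo_fixed = NULL,
                     up_target = NULL, lo_target = NULL, ngrid = 241L) {
  K <- length(frac)
  up_fixed <- up_fixed %||% rep(Inf, K)
  lo_fixed <- lo_fixed %||% rep(-Inf, K)
  up_target <- up_target %||% rep(NA_real_, K)
  lo_target <- lo_target %||% rep(NA_real_, K)
  upper <- up_fixed; lower <- lo_fixed
  p_up <- p_lo <- numeric(K)
  capped <- FALSE
  x <- h <- w <- NULL
  tprev <- 0
  for (k in seq_len(K)) {
    dt <- frac[k] - tprev
    if (dt <= 0) stop("information fractions must be strictly increasing")
    sdk <- sqrt(dt)
    mu <- if (k == 1L) drift * dt else x + drift * dt
    pup_fun <- if (k == 1L) {
      function(hs) stats::pnorm(hs, mu, sdk, lower.tail = FALSE)
    } else {
      function(hs) sum(w * h * stats::pnorm(hs, mu, sdk, lower.tail = FALSE))
    }
    plo_fun <- if (k == 1L) {
      function(ls) stats::pnorm(ls, mu, sdk)
    } else {
      function(ls) sum(w * h * stats::pnorm(ls, mu, sdk))
    }
    rt <- sqrt(frac[k])
    if (!is.na(up_target[k])) {
      tgt <- up_target[k]
      if (tgt <= 0) stop("efficacy spending increment must be positive")
      f <- function(z) pup_fun(z * rt) - tgt
      br <- drift * rt + c(-.GS_TRUNC - 1, .GS_TRUNC + 1)
      if (f(br[1]) < 0)
        stop("efficacy spending increment exceeds available probability mass")
      upper[k] <- stats::uniroot(f, br, tol = 1e-9)$root
    }
    if (!is.na(lo_target[k])) {
      tgt <- lo_target[k]
      if (tgt <= 0) stop("futility spending increment must be positive")
      f <- function(z) plo_fun(z * rt) - tgt
      br <- drift * rt + c(-.GS_TRUNC - 1, .GS_TRUNC + 1)
      if (f(br[2]) < 0) {
        # remaining continuation mass smaller than the increment (extreme
        # drift): take all of it rather than fail
        lower[k] <- if (is.finite(upper[k])) upper[k] else br[2]
        capped <- TRUE
      } else {
        lower[k] <- stats::uniroot(f, br, tol = 1e-9)$root
      }
      if (is.finite(upper[k]) && lower[k] > upper[k]) {
        lower[k] <- upper[k]   # futility may never exceed efficacy
        capped <- TRUE
      }
    }
    hi_s <- if (is.finite(upper[k])) upper[k] * rt else Inf
    lo_s <- if (is.finite(lower[k])) lower[k] * rt else -Inf
    p_up[k] <- if (is.finite(hi_s)) pup_fun(hi_s) else 0
    p_lo[k] <- if (is.finite(lo_s)) plo_fun(lo_s) else 0
    glo <- max(lo_s, min(mu) - .GS_TRUNC * sdk)
    ghi <- min(hi_s, max(mu) + .GS_TRUNC * sdk)
    if (ghi <= glo) {            # continuation region empty: all mass stopped
      x <- (glo + ghi) / 2; h <- 0; w <- 0
    } else {
      y <- seq(glo, ghi, length.out = ngrid)
      h <- if (k == 1L) {
        stats::dnorm(y, mu, sdk)
      } else {
        as.vector(stats::dnorm(outer(y, mu, "-") / sdk) %*% (w * h)) / sdk
      }
      x <- y
      w <- .simpson_weights(ngrid, y[2] - y[1])
    }
    tprev <- frac[k]
  }
  list(upper = upper, lower = lower, p_up = p_up, p_lo = p_lo,
       p_continue = sum(w * h), futility_capped = capped)
}

# efficacy z-boundaries under the null, ignoring futility (nonbinding)
.efficacy_bounds <- function(eff_frac, alpha_side, gamma_alpha, ngrid = 241L) {
  cum <- alpha_side * eff_frac^gamma_alpha
  cum[length(cum)] <- alpha_side          # t = 1 exactly exhausts the budget
  inc <- diff(c(0, cum))
  .gs_pass(eff_frac, drift = 0, up_target = inc, ngrid = ngrid)$upper
}

# futility z-boundaries given efficacy bounds, at a given drift;
# also returns total efficacy-crossing probability (power) at that drift
.futility_pass <- function(frac, eff_z, beta_total, gamma_beta, drift,
                           fut_mask, ngrid = 241L) {
  cum <- beta_total * frac^gamma_beta
  lo_target <- ifelse(fut_mask, diff(c(0, cum)), NA_real_)
  lo_target[length(frac)] <- NA_real_     # final look: non-rejection = failure
  ps <- .gs_pass(frac, drift = drift, up_fixed = eff_z,
                 lo_target = lo_target, ngrid = ngrid)
  ps$power <- sum(ps$p_up)
  ps
}

.drift_fixed <- function(spec) {
  a <- spec$alpha_total / spec$sided
  stats::qnorm(1 - a) + stats::qnorm(1 - spec$beta_total)
}

#' Group-sequential boundaries from an error-spending specification
#'
#' Computes per-look efficacy and nonbinding futility z-boundaries by
#' recursive numerical integration of the sequential z-process. Efficacy
#' boundaries spend `alpha * t^gamma_alpha` under the null across the
#' efficacy looks (futility ignored, i.e. nonbinding alpha control);
#' futility boundaries spend `beta * t^gamma_beta` under the design-drift
#' alternative with efficacy stopping respected.
#'
#' When `fixed_D` (the fixed-design event count) is supplied, the maximum
#' event count is inflated to the smallest integer restoring power
#' `1 - beta_total` at the design effect, look fractions are refined to the
#' attainable event counts `ceiling(t_k * D) / D`, and boundaries are
#' recomputed at the refined fractions.
#'
#' @param schedule a [look_schedule()].
#' @param spec a [spending_spec()].
#' @param fixed_D optional fixed-design event count from [required_events()].
#' @param drift optional explicit drift (expected z at full information) at
#'   which futility boundaries are computed; by default the drift solving
#'   power = 1 - beta_total.
#' @param ngrid integration grid size per look.
#' @return an object of class `gs_design`.
#' @export
compute_boundaries <- function(schedule, spec, fixed_D = NULL, drift = NULL,
                               ngrid = 241L) {
  stopifnot(inherits(schedule, "look_schedule"), inherits(spec, "spending_spec"))
  a_side <- spec$alpha_total / spec$sided
  d_fix <- .drift_fixed(spec)

  build <- function(frac, eff_mask, fut_mask, dr) {
    eff_z <- rep(NA_real_, length(frac))
    eff_z[eff_mask] <- .efficacy_bounds(frac[eff_mask], a_side,
                                        spec$gamma_alpha, ngrid)
    fut_z <- rep(NA_real_, length(frac))
    up_fixed <- ifelse(eff_mask, eff_z, Inf)
    capped <- FALSE
    if (any(fut_mask)) {
      fp <- .futility_pass(frac, up_fixed, spec$beta_total, spec$gamma_beta,
                           dr, fut_mask, ngrid)
      fut_z[fut_mask] <- fp$lower[fut_mask]
      capped <- fp$futility_capped
    }
    list(eff_z = eff_z, fut_z = fut_z, capped = capped)
  }

  frac <- schedule$frac
  eff_mask <- schedule$efficacy
  fut_mask <- schedule$futility

  power_at <- function(dr) {
    b <- build(frac, eff_mask, fut_mask, dr)
    up_fixed <- ifelse(eff_mask, b$eff_z, Inf)
    lo_fixed <- ifelse(fut_mask & is.finite(b$fut_z), b$fut_z, -Inf)
    ps <- .gs_pass(frac, drift = dr, up_fixed = up_fixed, lo_fixed = lo_fixed,
                   ngrid = ngrid)
    sum(ps$p_up)
  }

  if (is.null(drift)) {
    if (any(fut_mask)) {
      f <- function(dr) power_at(dr) - (1 - spec$beta_total)
      dstar <- stats::uniroot(f, c(d_fix * 0.999, d_fix * 3), tol = 1e-7)$root
    } else dstar <- d_fix
  } else dstar <- drift

  inflation <- (dstar / d_fix)^2
  max_events <- NA_integer_
  events <- rep(NA_integer_, length(frac))
  if (!is.null(fixed_D)) {
    .check_number(fixed_D, "fixed_D", 1, Inf, integer = TRUE)
    max_events <- as.integer(ceiling(fixed_D * inflation - 1e-9))
    inflation <- max_events / fixed_D
    dstar <- d_fix * sqrt(max_events / fixed_D)
    events <- as.integer(ceiling(frac * max_events - 1e-9))
    if (any(diff(events) <= 0))
      stop("look fractions too close: duplicated event targets at D = ",
           max_events)
    frac <- events / max_events
  }

  b <- build(frac, eff_mask, fut_mask, dstar)
  cum_alpha <- ifelse(eff_mask, a_side * frac^spec$gamma_alpha, NA_real_)
  if (any(eff_mask)) cum_alpha[length(frac)] <- a_side
  cum_beta <- ifelse(fut_mask, spec$beta_total * frac^spec$gamma_beta, NA_real_)

  structure(list(frac = frac, events = events,
                 efficacy = eff_mask, futility = fut_mask,
                 efficacy_z = b$eff_z, futility_z = b$fut_z,
                 cum_alpha = cum_alpha, cum_beta = cum_beta,
                 inflation_factor = inflation, max_events = max_events,
                 drift = dstar, spec = spec,
                 futility_capped = b$capped,
                 superiority_fraction = schedule$superiority_fraction),
            class = "gs_design")
}

#' @export
print.gs_design <- function(x, ...) {
  cat(sprintf("Group-sequential design: %d looks, alpha = %g (%d-sided), power = %g\n",
              length(x$frac), x$spec$alpha_total, x$spec$sided,
              1 - x$spec$beta_total))
  cat(sprintf("  gamma_alpha = %g, gamma_beta = %g, inflation = %.4f, max events = %s\n",
              x$spec$gamma_alpha, x$spec$gamma_beta, x$inflation_factor,
              ifelse(is.na(x$max_events), "NA", x$max_events)))
  print(design_table(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Boundary table of a design
#'
#' @param design a `gs_design`.
#' @return a data frame with one row per look: look, information_fraction,
#'   events, efficacy_z, futility_z, cumulative_alpha_spent,
#'   cumulative_beta_spent.
#' @export
design_table <- function(design) {
  stopifnot(inherits(design, "gs_design"))
  data.frame(look = seq_along(design$frac),
             information_fraction = design$frac,
             events = design$events,
             efficacy_z = design$efficacy_z,
             futility_z = design$futility_z,
             cumulative_alpha_spent = design$cum_alpha,
             cumulative_beta_spent = design$cum_beta)
}

#' Per-look stopping probabilities of a design at a given drift
#'
#' Runs the boundary recursion with both boundary families fixed and returns
#' the probability of stopping at each look for efficacy or futility
#' (non-rejection at the final look counts as the futility outcome), together
#' with the expected information fraction at stopping.
#'
#' @param design a `gs_design`.
#' @param drift expected value of the z-statistic at full information
#'   (for a survival trial, `-log(HR) * sqrt(D * r) / (1 + r)`).
#' @param ignore_futility if `TRUE`, futility boundaries are dropped
#'   (overruled), giving the nonbinding worst-case efficacy crossing; under
#'   the null this equals the full alpha budget.
#' @param ngrid integration grid size.
#' @return a data frame (one row per look) with attributes `total_efficacy`,
#'   `total_futility` and `expected_information`.
#' @export
crossing_probabilities <- function(design, drift, ignore_futility = FALSE,
                                   ngrid = 241L) {
  stopifnot(inherits(design, "gs_design"))
  K <- length(design$frac)
  up <- ifelse(design$efficacy & is.finite(design$efficacy_z),
               design$efficacy_z, Inf)
  lo <- if (ignore_futility) rep(-Inf, K)
        else ifelse(design$futility & is.finite(design$futility_z),
                    design$futility_z, -Inf)
  ps <- .gs_pass(design$frac, drift = drift, up_fixed = up, lo_fixed = lo,
                 ngrid = ngrid)
  p_fut <- ps$p_lo
  p_fut[K] <- p_fut[K] + ps$p_continue    # final non-rejection
  out <- data.frame(look = seq_len(K), information_fraction = design$frac,
                    p_efficacy = ps$p_up, p_futility = p_fut)
  attr(out, "total_efficacy") <- sum(ps$p_up)
  attr(out, "total_futility") <- sum(p_fut)
  attr(out, "expected_information") <- sum(design$frac * (ps$p_up + p_fut))
  out
}

#' Fixed-design event count (Schoenfeld formula)
#'
#' `D = (z_{1-alpha} + z_{1-beta})^2 (1+r)^2 / (r log(HR)^2)`, rounded up.
#'
#' @param design_hr design hazard ratio (not 1).
#' @param alpha_total type-I error; one-sided unless `sided = 2`.
#' @param beta_total type-II error.
#' @param allocation_ratio treated:control allocation ratio r.
#' @param sided 1 or 2.
#' @return integer event count.
#' @export
required_events <- function(design_hr, alpha_total = 0.025, beta_total = 0.1,
                            allocation_ratio = 1, sided = 1L) {
  .check_number(design_hr, "design_hr", 0, Inf, TRUE)
  if (abs(design_hr - 1) < 1e-12)
    stop("event count undefined at design_hr = 1")
  r <- .check_number(allocation_ratio, "allocation_ratio", 0, Inf, TRUE)
  za <- stats::qnorm(1 - alpha_total / sided)
  zb <- stats::qnorm(1 - beta_total)
  as.integer(ceiling((za + zb)^2 * (1 + r)^2 / (r * log(design_hr)^2) - 1e-9))
}

#' Inflate the maximum event count of a group-sequential design
#'
#' Finds the smallest event count such that, following both boundary
#' families, power at the design drift is at least `1 - beta_total`.
#'
#' @param fixed_D fixed-design event count.
#' @param schedule a [look_schedule()].
#' @param spec a [spending_spec()].
#' @return list with `max_events`, `inflation_factor`, and the full `design`.
#' @export
inflate_max_events <- function(fixed_D, schedule, spec) {
  d <- compute_boundaries(schedule, spec, fixed_D = fixed_D)
  list(max_events = d$max_events, inflation_factor = d$inflation_factor,
       design = d)
}

# ---- serialization ----------------------------------------------------------

#' Write / read a design as structured text (JSON)
#' @param design a `gs_design`.
#' @param path file path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "gs_design"))
  x <- unclass(design)
  x$spec <- unclass(x$spec)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$spec <- do.call(spending_spec, x$spec)
  x$events <- if (all(is.na(x$events))) rep(NA_integer_, length(x$frac))
              else as.integer(x$events)
  x$max_events <- if (is.null(x$max_events) || is.na(x$max_events))
    NA_integer_ else as.integer(x$max_events)
  for (f in c("efficacy_z", "futility_z", "cum_alpha", "cum_beta"))
    x[[f]] <- as.numeric(x[[f]])
  structure(x, class = "gs_design")
}

#' Export a design's boundary table as CSV
#' @param design a `gs_design`.
#' @param path file path.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design_table(design), path, row.names = FALSE, na = "")
  invisible(path)
}
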
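---
title: "Optimizing interim-analysis schemes for event-driven survival trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing interim-analysis schemes for event-driven survival trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optinterim)
```

## The problem

An event-driven two-arm survival trial analyzes its primary endpoint when a
prespecified number of events `D` has accrued. Interim analyses let the
trial stop earlier — for futility when a benefit has become implausible, or
for superiority when the evidence already clears the multiplicity-adjusted
threshold. How much earlier depends entirely on *when* the looks are placed
and *how strict* their decision rules are, and those choices are usually
made by convention. In indications where most programmes fail, conventions
tuned to optimistic effect assumptions waste patients and time.

`optinterim` treats the look schedule and the decision rules as free
parameters and searches for the combination with the best expected operating
characteristics, averaging over an evidence-based distribution of treatment
effects rather than a single assumed hazard ratio.

## Group-sequential machinery

**Canonical process.** At information fraction `t_k = d_k / D` the log-rank
z-statistic behaves asymptotically like a Gaussian process with
`E[z_k] = δ √t_k` and `cov(z_j, z_k) = √(t_j / t_k)`, where the drift
`δ = −log(HR) √(D r) / (1 + r)` for allocation ratio `r` (Schoenfeld
approximation; `δ = −log(HR) √D / 2` at 1:1). Equivalently the B-value
`s_k = z_k √t_k` has independent normal increments — the representation used
throughout the integration code.

**Spending functions.** Both error budgets follow the Kim–DeMets power
family `f(t) = ε t^γ`. The efficacy exponent `γ_A` spans 2.00–3.00 and the
futility exponent `γ_B` spans 0.75–3.00 in the default grid (steps 0.25):
small `γ` approximates a Pocock-type rule (lenient early), large `γ` an
O'Brien–Fleming-type rule (strict early). The `γ_A` grid step is not
prescribed anywhere, so it mirrors the futility step.

**Boundaries.** Efficacy boundaries are solved under the null so that the
incremental crossing probability at each efficacy look equals the α spent
since the previous one, *ignoring futility boundaries*: futility is
nonbinding, so α-control never relies on stopping for futility, and
overruling a futility signal cannot inflate type-I error. Futility
boundaries are then solved under the design drift so incremental lower
crossings match the β-spending increments, with efficacy stopping respected.
Efficacy is tested only at the 60% look and at the final analysis; every
non-final look tests futility; failing to reject at the final analysis is
the futility outcome.

**Event inflation.** Spending information on interim looks costs power, so
the maximum event count is inflated: the drift `δ*` restoring power
`1 − β` is found by root-finding on the recursion, and
`D = ⌈D_fixed (δ*/δ_fixed)²⌉` with `δ_fixed = z_{1−α} + z_{1−β}`. Because
analyses happen at integer event counts, look fractions are refined to
`⌈t_k D⌉ / D` and boundaries recomputed at the refined fractions, which
keeps the simulated information scale and the boundary scale identical.
Integer rounding leaves attained power in `[1−β, 1−β + ~0.005]`.

**Numerics.** The continuation density is propagated on a 241-point Simpson
grid per look, truncated at ±8.5 increment standard deviations; boundary
values are solved by `uniroot` to 1e-9 on the z-scale. Against a 10⁶-replicate
Monte-Carlo simulation of the correlated z-process, per-look crossing
probabilities agree to ~1e-4 (three Monte-Carlo standard errors); total null
efficacy crossing equals α to better than 1e-5. If a futility spending
increment exceeds the remaining continuation mass (possible at extreme
drifts probed during root-finding) the boundary is capped at the efficacy
boundary and flagged, rather than failing.

## The mixture prior on the treatment effect

Design-stage evidence enters as a two-component normal mixture on the log
hazard ratio:

* **Success component** (probability `p`): centered on the design log-HR
  with the standard error implied by earlier data. From a historically
  controlled cohort with per-arm sample sizes, medians and a fixed follow-up
  window, expected event counts are `n(1 − exp(−(c/λ)^ρ))` with
  `λ = median / (log 2)^{1/ρ}`, and `SE = 2/√(d_total)` (the pooled 1:1
  approximation — the per-arm variant `√(1/d₁ + 1/d₂)` does *not* reproduce
  the published 0.335 from the published cohort summaries, so the pooled
  form is used). For the diaphragm-pacing cohort (43 + 43 patients, medians
  21.4/37.5 months, 24-month follow-up, ρ = 2) this gives expected events
  25.0 + 10.6 and SE 0.335.
* **Futility component** (probability `1 − p`): same center, variance
  inflated 10-fold (SE 1.06 for the pacing cohort), expressing that with a
  7.1% historical success rate one should be far less certain than the
  early-phase data suggest.

Two modelling points were genuinely open:

* The mixture is implemented as a two-point distribution over the SE values
  {0.335, 1.06} with weights {p, 1−p} — i.e. a two-component normal mixture
  for the log-HR — because exactly two SEs with complementary probabilities
  are enumerated in the source material. A 75% interval of roughly
  HR 0.23–0.87 quoted there for a design HR of 0.45 is not reproduced by
  this reading under any obvious quantile convention (the central 75%
  interval of the mixture is wider); the two-point reading is retained
  because it is the only one fully determined by the stated quantities.
* The futility component's center defaults to the design effect
  (`theta_futility = theta_design`), so the two components differ only in
  spread; a null-centered futility scenario (`theta_futility = 0`, or
  `"null"` in a configuration file) is available. Centering both on the
  design effect is the more conservative reading for futility monitoring:
  it makes harmful-effect draws no more likely than the inflated variance
  alone implies.

Effect conversions for function-scale phase-II data are provided:
each ALSFRS-R point of benefit multiplies the hazard by `1 − 0.119`
(`alsfrs_to_hr()`); an externally estimated SE (e.g. 0.147 for the
ceftriaxone programme) can be supplied directly, since its derivation
depends on unreported phase-II inputs.

## Trial simulation

Event times are Weibull with shape `ρ` (default 2, increasing hazard —
appropriate for ALS survival); the control scale is set by the configured
median and the treated scale is `λ_c · HR^{−1/ρ}`, which makes hazards
exactly proportional, so the log-rank/Cox estimand equals the configured HR.
Enrollment is uniform over the accrual window; there is no loss to follow-up
and no delayed treatment effect (both deliberate idealizations of the
planning model, stated as such). Analyses occur exactly when the event
target is reached — optimistic about data-cleaning lag, again by design.

The sequential log-rank statistic is computed on data administratively
censored at each analysis time, with `z > 0` favoring treatment. Null
calibration (10⁴ replicates) gives mean |z| < 0.03 and variance within
[0.95, 1.05]; the statistic agrees with `survival::survdiff` to 1e-8 on
censored data.

A trial that can never reach a look's event target (target exceeding the
number of randomized patients) is scored at the calendar time its follow-up
is exhausted and flagged (`capped`), and such schemes are in practice
removed by the duration exclusion below.

## Scheme search

The default grid takes all 4- and 5-look futility subsets of
{0.30, …, 0.90} containing the fixed 0.60 superiority look — requiring 0.60
in every timing set matches the fixed superiority analysis and yields the
1,750-scheme pre-exclusion candidate count consistent with the published
post-exclusion counts — crossed with both spending grids. Schemes whose
*maximum* duration (expected calendar time to their inflated `D` under the
design assumptions, computed by deterministic quadrature of the
expected-event curve, not by simulation) exceeds 1.10× the no-interim
design's duration are excluded; the exclusion rule's operationalization is
not uniquely determined by its source, and the deterministic reading was
chosen because it is seed-free and matches the "maximum" (not realized)
phrasing. Reproduction of the published per-trial scheme counts
(797/183/1,351) additionally requires protocol inputs that were never
published, so it is treated as exploratory, not as a test target.

Evaluation uses common random numbers: per replicate, one effect is drawn
from the mixture, one trial is simulated, and *every* scheme is scored on
that same trial, so between-scheme comparisons are free of between-replicate
noise. Replicates use index-derived RNG streams (`seed + 7919·i`), making
results independent of evaluation order — the serial/parallel equivalence
contract — though no parallel backend is shipped. The planning default is
10,000 replicates; desk-scale runs use fewer. The winner minimizes mean
duration (or sample size or exposure); ties break by smaller mean sample
size, then fewer looks, then lexicographic timing.

Selection inherits a winner's-curse bias: the selected scheme's estimated
criterion is optimistically biased by the magnitude of Monte-Carlo noise at
the chosen replicate count. On the 12-scheme toy grid at 2,000 replicates,
adjacent schemes can be statistical dead heats (mean durations within
0.003 months); the selected optimum is nevertheless stable under doubling of
replicates because the common-random-number estimates are strongly
correlated across replicate counts.

## Retrospective monitoring and conditional power

Published per-look summaries are reconstructed as
`SE = log(hi/lo)/(2·1.96)`, `z = −log(HR)/SE`, implied events `4/SE²`
(Wald-interval convention). When observed looks carry information fractions
they are matched to the nearest design look (mismatch > 0.05 is an error);
without fractions they are matched by order, with implied fractions logged —
necessary because an implied event count from an early look rarely pins down
the planned fraction when the planned maximum is unknown.

Conditional power uses the B-value decomposition:
`CP = Φ((z√t + δ(1−t) − u_final)/√(1−t))` against the final efficacy
boundary, with the drift taken from an assumed HR at the design's maximum
event count. A published conditional-power value of 6.3% for the
diaphragm-pacing trial's first look could not be pinned to a unique
formulation (it depends on that trial's unpublished planned event count and
possibly on the prior), so the standard formulation above is implemented and
the drift assumption is exposed as a parameter; the value is deliberately
not a test target.

## What the synthetic world does and does not establish

The simulator *is* the planning model: Weibull proportional hazards, uniform
accrual, no dropout, instant analyses. Green tests establish internal
consistency (boundaries spend exactly what they promise; the simulation
pipeline attains nominal α and power; the optimizer's orderings are
reproducible and beat reference designs under the stated prior) — they do
not establish that real trials obey proportional hazards, that real
enrollment is uniform, or that the published protocol quantities missing
from the public record (per-trial planned n, accrual, α, power) match the
clearly labeled placeholders shipped in the `dipals`/`respistimals`/
`ceftriaxone` fixtures. Those placeholders must be replaced with protocol
values before any fixture is used for a real planning decision; published
percentage reductions in duration or sample size for the three historical
trials are not reproducible without the patient-level data and are not
asserted anywhere in the test suite.

## Known limitations

* Non-proportional hazards (including delayed effects), dropout, cure
  fractions, competing risks and covariate adjustment are out of scope.
* Only one interim superiority analysis is supported (plus the final), at a
  configurable fraction; sidedness is one-sided by default with a symmetric
  two-sided option.
* Sample-size re-estimation, enrichment and randomization-ratio adaptation
  are not implemented.
* The conditional-power and boundary calculations rely on the asymptotic
  canonical joint distribution; at very small event counts (< ~20) the
  log-rank statistic is visibly discrete and the normal approximation is
  rough.
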
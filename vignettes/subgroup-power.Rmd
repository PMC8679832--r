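---
title: "Power of subgroup analyses in meta-analysis: models, solvers and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power of subgroup analyses in meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subpower)
```

## The question

A meta-analysis that comfortably detects a pooled effect is usually far too
small to detect a *difference* between subgroups of studies. `subpower`
makes that statement quantitative for standardized mean differences (SMDs)
under a random-effects model: analytic power for the pooled-effect test and
for the between-subgroup moderator test, solvers for the number of studies
a design needs, and a simulator that checks what the analytic numbers do
and do not promise.

## Effect-size model and its assumptions

Every study is a two-arm comparison with `study_size` participants in
total. Two assumptions are baked in and worth stating prominently:

* **Equal arms.** `study_size` is split equally, n₁ = n₂ = N/2. A stated
  "50 participants per study" is read as 25 per arm. Odd study sizes are
  rejected rather than silently floored; callers can pre-round.
* **Asymptotic variance, no small-sample correction.** The sampling
  variance of an SMD d is v(d) = (n₁+n₂)/(n₁n₂) + d²/(2(n₁+n₂)). The
  Hedges small-sample factor J = 1 − 3/(4(N−2)−1) is applied only inside
  the simulator, where effects are *estimated*; the analytic path works
  with true design values, for which the asymptotic formula is the model.

Heterogeneity is specified as I², the proportion of total variability in
effect estimates due to between-study variation. Given a typical
within-study variance v, the implied between-study variance is
τ² = v·I²/(1 − I²), so each study's total variance inflates to
v* = v/(1 − I²). τ² is treated as *known* throughout the analytic path
(the Wald/noncentral framework); estimation error in τ² is a simulator
topic, below.

## The two tests

**Pooled effect.** The two-sided z-test of the pooled SMD at level α has
noncentrality λ = |d|/√(v*(d)/k) and power
1 − Φ(z₁₋α/₂ − λ) + Φ(−z₁₋α/₂ − λ). At d = 0 power equals α exactly.

**Moderator (Q-between).** With p subgroups, true effects d_j and study
shares p_j, fixed weights w_j = p_j·k / v*(d_j) give the noncentrality

λ = Σ_j w_j (d_j − d̄)², d̄ = Σ w_j d_j / Σ w_j,

and power is the upper tail of the noncentral χ²(p−1, λ) beyond the
central 1−α quantile (`noncentral_chisq_sf()`, a validated wrapper over
`stats::pchisq`). Three modelling choices matter:

* each subgroup's *own* true effect enters its variance (no common
  "typical" variance across subgroups);
* the test is the fixed-weights Q-between chi-square, not a
  Knapp–Hartung/F variant;
* fractional per-subgroup study counts p_j·k are allowed in the power
  formula — integrality is purely a solver constraint.

For p = 2 the chi-square power is identical (to 1e−9, tested) to the
two-sided z-test on the difference d₂ − d₁ with variance
v*₁/k₁ + v*₂/k₂.

## The solver and its constraints

`required_k_main()` / `required_k_subgroup()` return the smallest k with
power ≥ target. Power is strictly increasing in k, so a doubling bracket
plus integer bisection is exact; the search is capped at 10⁶ studies and
fails loudly (`subpower_not_achievable`) beyond that — a zero subgroup
difference diverges. Achieved power is kept at full precision; rounding
happens only in display. Three integrality constraints are exposed because
published requirements differ by exactly this choice: `any_integer`
(k = 21 for the reference two-subgroup scenario below), `even` (k = 22 —
every balanced subgroup gets a whole number of studies), and
`multiple_of_groups`. Neither 21 nor 22 is privileged; both are reported by
the package and tested.

### The reference scenario and the tunable parameters

Defaults describe an "average" intervention meta-analysis and are used
throughout the tests: `study_size = 50` participants (unitless SMD scale,
25 per arm), `i2 = 0.5` (a moderate value; average heterogeneity in
psychology has been estimated around 74%, which is why grids extend to
0.75), `alpha = 0.05` two-sided, `target_power = 0.80`, subgroup effects
0.1 and 0.6. With those values the package computes: main analysis k = 6;
moderator analysis k = 22 (even) / 21 (any integer); 28 at 90% power; 14
at I² = 25%; 42 at I² = 75% — identical λ = 8.0177 at 21/14/42, since k
scales linearly with the variance inflation at fixed λ.

### Anchoring a "difference of Δ"

Scenario grids (`required_k_grid()`) express subgroups as
(anchor, anchor + Δ). The anchor is a real parameter (default 0.1,
generalizing the 0.1-vs-0.6 reference scenario) because it genuinely
matters at the percent level: the anchor enters the variance d²/(2N)
term, so at Δ = 0.2 the any-integer requirement is 127 with anchor 0.1
but 126 with anchor 0.0. Published requirement tables rarely state their
anchor; comparisons at the last integer should not be over-read.

## What the simulator does

`empirical_power()` runs seeded Monte-Carlo meta-analyses. The
data-generating process is a reconstruction — the conventional one, since
no canonical process is mandated by the analytic model:

1. Study i in subgroup g(i) gets a true effect
   θᵢ = d_{g(i)} + Normal(0, τ²), with a single common τ² derived from I²
   at the *across-group mean* within-study variance. (The analytic side
   inflates each group's variance separately; the tests compare the two
   conventions explicitly — at the reference scenario the noncentralities
   agree to three decimals.)
2. Raw arms: N/2 observations per arm from unit-variance normals whose
   means differ by θᵢ; the Hedges-corrected SMD and its estimated variance
   are computed per study (`simulate_study()`).
3. The moderator test (`qb_test()`) or pooled z-test is run per replicate.

One root seed spawns an independent sub-seed per replicate, so results are
bit-identical for a given seed regardless of evaluation order.

### Three weighting modes, and the gaps they reveal

The `weights` argument decides how much the test is allowed to know:

* `"known"` — design within-study variances and true τ². This is *exactly*
  the sampling frame the analytic noncentral formulas describe, so it is
  the mode used to validate them: across the tested scenario grid the
  empirical rate matches analytic power within 3 Monte-Carlo standard
  errors (10,000 replicates for the reference scenarios).
* `"known_tau2"` (default) — estimated per-study variances, true τ².
  Estimating v̂ from N = 50 observations already costs real power relative
  to the analytic value. The result object always reports the paired
  analytic value next to the empirical rate, so the deviation is
  surfaced, never hidden.
* `"estimated"` — estimated variances and DerSimonian–Laird τ̂²
  re-estimated each replicate (`dersimonian_laird_tau2()`, the
  within-group residual-Q moment estimator; it matches an independent
  `metafor` meta-regression fit to 1e−10 in the tests). This is actual
  practice, and it is *anticonservative*: at the null with 20 studies and
  I² = 50% the moderator test rejects noticeably more than 5% (asserted
  as a property in the test suite). Analytic power values should
  therefore be read as what the idealized test achieves; the practical
  test at small k is both noisier and liberal.

## Numerical choices

* Search: doubling + integer bisection on the constraint lattice; ties go
  to the smallest k; no randomness anywhere in the analytic path.
* Degenerate inputs fail with typed conditions (`subpower_invalid_design`,
  `subpower_subgroup_spec`, `subpower_not_achievable`, …) rather than
  NA results.
* The main-vs-subgroup ratio (`ratio_to_main()`) defines the main-analysis
  effect as the *difference* between the two subgroup effects, and lets
  the main analysis keep its own target power (default: same as the
  subgroup target). A subgroup question examined at 90% power is most
  naturally contrasted with the headline main analysis powered at 80%,
  which is the comparison the reference numbers make (28 vs 6).
* CLI: I² is accepted on both proportion (0.5) and percentage (50) scales
  with an explicit value-greater-than-1 ⇒ percentage rule; every run
  echoes its fully resolved parameter set into the output, so reports are
  self-describing and round-trip back into an identical configuration.

## Problem sizes in the test suite

Analytic checks are instantaneous. Simulation tests use 10,000 replicates
for the reference-scenario validations and the null-size check, 100,000
draws for the single-study variance consistency check, and 1,500
replicates per scenario for the seven-scenario agreement grid — sizes at
which three Monte-Carlo standard errors are decisively smaller than the
effects being asserted.

## Known limitations

* SMD only; correlation or odds-ratio metrics, unequal arms, and
  cluster-randomized designs are out of scope.
* One categorical moderator at a time; no meta-regression, no
  Knapp–Hartung adjustment, no random-weights analytic power.
* The simulator's normal-arms process is a reconstruction; real
  meta-analyses add publication bias, unequal study sizes and non-normal
  outcomes that neither the analytic model nor the generator emulates —
  passing validation here shows the formulas are internally correct, not
  that any real meta-analysis meets their assumptions.
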
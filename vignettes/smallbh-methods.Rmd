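---
title: "Estimating under-5 mortality from small birth-history samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating under-5 mortality from small birth-history samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smallbh)
library(data.table)
```

## The problem

Complete birth histories (CBH) record, for each surveyed woman aged
15–49, every child's month of birth and — for children who died — the age
at death. Direct estimates of under-5 mortality (5q0) from CBH data are
the standard product of surveys like the DHS. When such estimates are
wanted for small domains, the effective number of women can fall to tens
or hundreds, and the statistical behaviour of the estimators at those
sizes is not obvious: a period containing no observed deaths contributes
an estimate of zero mortality, and pooling across time trades variance
for bias. `smallbh` implements the estimators, a microsimulation
generator with analytically known truth, and a subsampling validation
engine, so those trade-offs can be quantified end to end.

All dates are integer CMC-style month indices (months since January
1900, DHS's native encoding); the single conversion to decimal years
places each month at its midpoint, `year = 1900 + (cmc − 0.5)/12`.

## Child-month expansion

Each child contributes one record per month lived *and observed* under
age 5. A child alive at interview and born `m` months before it
contributes completed ages `0 .. min(59, m − 1)`; the interview month
itself is excluded because its end-state is unknown — the standard
demographic convention, shifting exposure by at most one month per
child. `death_age_months = d` means *completed months lived*: the child
died during their month of age `d`, so a death at `d = 0` yields exactly
one child-month ending dead, and a reported `d ≥ 60` counts as survival
through all 60 under-5 months. Months are atomic: there is no
partial-month (Kaplan–Meier-style) weighting, matching the monthly
survival-probability formulation below.

## The synthetic-cohort estimator

Ages are grouped as 0, 1–11, 12–23, 24–35, 36–47, 48–59 months
(`n_g` = 1, 11, 12, 12, 12, 12), intervals within which mortality is
roughly constant. Given any weighted set of child-months, each group's
monthly survival probability is the weighted fraction ending alive, and

$$ {}_5q_0 = 1 - \prod_g p_g^{\,n_g}. $$

Conventions where the procedure leaves choices open:

* **Empty age group → survival 1.** A group with zero weight contributes
  no mortality. This is what makes small samples biased *downward*: a
  10-woman sample often observes zero deaths in some group, never
  "extra" deaths, and mortality not observed is mortality not counted.
  The validation study reproduces exactly this signature.
* **All-zero weight → no estimate**, rather than an estimate of 0; the
  period or year simply yields no row.
* **Periods** of length L years tile backwards from the most recent
  interview month, the newest period ending with (including) the anchor
  month: period k covers months `(anchor − 12L(k+1), anchor − 12L·k]`.
  Estimates sit at the period midpoint in decimal years.
* **Moving windows**: target year T sits at mid-year T + 0.5; flat
  weights are 1 for `|t − (T+0.5)| ≤ x/2` (boundary inclusive, though at
  month resolution with x ∈ {5, 10, 20} the boundary is never hit
  exactly), triangle weights decay linearly and are exactly 0 at x/2.
  Windows truncated at the survey date need no renormalisation — the
  estimator is a weighted proportion — and estimates are emitted
  wherever total weight is positive, with exposure recorded so thin
  tails can be filtered.

Because the flat kernel reduces to unit weights, a flat window covering
exactly the months of a standard period reproduces the period estimate
bit for bit; the test suite asserts this, and checks both estimators
against an independent per-child brute-force enumeration on hundreds of
random tiny surveys (bitwise for integer-weight paths, to 1e−12 for
triangle weights, whose floating sums accumulate in a different order).

## The microsimulation generator

The generator produces DHS-like surveys whose true mortality is known in
closed form, standing in for restricted survey data.

* **Mortality.** An age pattern `h0_g` (default ∝ 28, 8, 3, 2, 1.5, 1 —
  front-loaded infant mortality, a qualitatively realistic shape; only
  ratios matter) is scaled at every calendar year by
  `k(y) = −log(1 − q5(y)) / Σ_g n_g h0_g`, so the period survival
  product equals `1 − q5(y)` *exactly* — the construction identity
  `analytic_q5(hazards_at(y)) ≡ target_q5(y)`, which holds to machine
  precision and anchors all parameter-recovery tests. The target is
  constant or log-linear between two endpoints (mortality declines
  roughly exponentially in most settings), clamped outside.
* **Deaths are hazard-consistent**: each child faces monthly probability
  `1 − exp(−h)` with `h` evaluated at the *calendar* year of that month
  (period, not cohort, mortality) — so the generator and the estimators
  agree on what 5q0 means, and recovery tests are clean.
* **Fertility** is deliberately simple: monthly birth hazards by
  five-year maternal age band (defaults equivalent to age-specific
  fertility rates 0.12, 0.25, 0.25, 0.20, 0.15, 0.07, 0.02 per
  woman-year — TFR ≈ 5, typical of high-mortality settings), suppressed
  for 9 months after each birth. Fertility only shapes how much exposure
  exists at each lag before the survey; the study's conclusions are
  driven by mortality and sample size.
* **Women** are interviewed at one common month, ages uniform over
  15–49. Survivors past age 5 and deaths above age 5 are recorded simply
  as alive at survey (mortality above 5 is not modelled and the
  estimators never use it).
* **Implementation**: the simulation advances month by month, updating
  all women (then all children) in vectorised sweeps from one seeded
  stream. This is exactly reproducible given the seed and fast enough
  for 50,000-woman surveys in seconds; the alternative of per-woman RNG
  streams would buy order-independence that nothing here needs at the
  cost of a scalar event loop.

What the generator does *not* emulate: recall bias, age heaping and date
displacement, HIV-related survivorship selection, twins, sampling
weights, household clustering. Passing tests on synthetic data therefore
demonstrate the estimators' *sampling* behaviour — bias and error as
functions of sample size and pooling — not robustness to reporting
error, which real birth histories add on top.

## The validation engine

Per survey: truth = standard estimator with two-year periods on the full
sample, linearly interpolated between knots and never extrapolated;
estimate–truth pairs outside the knot span are dropped. Then 500 samples
of 10, 50, 100, 500 and 1,000 women are drawn without replacement (women,
not children — childless women count toward n), every configured method
runs on every sample, and each matched (sample, method, year) record is
scored with error `ê − q`, relative error `(ê − q)/q`, and their absolute
values. Summaries are unweighted means over matched records, with 2.5th
and 97.5th percentiles of the signed error. Strata follow the
conventional bins: true mortality <50, 50–100, 100–150, 150–200, >200
deaths per 1,000 (half-open on the right, decided here since only the
labels are conventional) and two-year lags 0–1, …, 24–25 years before
the survey (estimates nominally after an early-fielded survey clamp to
lag 0). Records with true mortality exactly 0 — possible in tiny
synthetic surveys — are dropped from relative-metric means and counted.

Pooling repeated surveys of one country concatenates full samples for
the truth (periods anchored at the latest interview) and draws n women
*per survey* per replicate, so nominal size 10 with three surveys
estimates from 30 women; records carry `n_surveys` for stratified
summaries.

Every sample's seed derives deterministically from (master seed, survey,
size, replicate), so any cell of the study can be re-run in isolation;
the engine tallies child-months once per survey and computes all
replicates of a size in one grouped pass, which the tests verify is
identical to calling the public estimators sample by sample.

## Study conditions and problem sizes

The packaged study uses five simulated surveys of 4,000 women each — two
countries, one with three surveys (2000, 2005, 2010) and one with two
(2003, 2008), with log-linear 5q0 declines 0.25→0.10 and 0.20→0.12 over
1975–2010 — sizes comparable to the smaller national surveys the methods
are used on, and large enough that the full-sample truth is stable while
500 × 5 subsamples per survey remain cheap. Parameter-recovery checks
use a 50,000-woman survey with constant 5q0 = 0.150 and assert recovery
within ±0.01 for period midpoints between 2.5 and 25 years before the
interview: the 25-year bound is the span the methods target (it is the
moving-window default and the outermost validation stratum), and beyond
it the uniform 15–49 age structure leaves structurally thin fertility
exposure — a woman can only contribute births 30+ years back if she was
interviewed near 49 and gave birth near 15 — so deviations there
measure exposure, not estimator fidelity. The most recent half-period
(midpoint < 2.5 years) is excluded for the symmetric reason that its
period is only partially elapsed.

## Known limitations

* Relative errors explode as true mortality approaches zero; comparisons
  across mortality strata should use the absolute metrics alongside.
* The standard estimator emits no value for empty periods, so
  small-sample series have gaps rather than zeros; consumers averaging
  over series should use the matched-record summaries, which handle this
  by construction.
* Period-boundary placement (anchored at the interview month rather than
  calendar-year boundaries) follows the anchor convention stated above;
  alternative alignments shift estimates by at most half a period
  length.
* Summary birth histories (children ever born / surviving, analysed via
  regression-calibrated coefficients) are out of scope: the required
  published coefficient sets are external to this package.
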
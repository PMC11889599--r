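---
title: "Simulating platform trials with shared concurrent controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating platform trials with shared concurrent controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platformsim)
library(dplyr)
```

## The design problem

When several candidate drugs for the same disease are ready for
confirmatory testing — the motivating setting is mortality among
hospitalized patients during an infectious-disease pandemic — three trial
architectures compete:

* **Stand-alone trials**: one conventional two-arm RCT per drug, each with
  its own placebo group. Four drugs at 435 patients per arm cost
  4 × 870 = 3480 patients.
* **Multi-arm trial (MAT)**: all drugs and a single shared placebo enroll
  over one common period. With equal (1:1:1:1:1) allocation the total is
  5 × 435 = 2175; with a double-weighted placebo (1:1:1:1:2) it is
  4 × 435 + 870 = 2610.
* **Platform trial (PT)**: drugs join an ongoing trial over time — here
  either one per month, or at uniformly random times — and leave when their
  planned enrollment completes. The shared placebo enrolls for as long as
  any drug arm is open, so its total size is not fixed in advance.

`platformsim` simulates all seven benchmark designs at monthly granularity
and estimates their operating characteristics: type I error rate per drug,
group-specific power (probability of declaring a given effective drug
efficacious), overall power (at least one effective drug declared), and the
placebo sample sizes that unequal allocation buys them with.

## The simulation model

One replicate proceeds month by month:

1. **Accrual.** A Poisson(`accrual_mean`) number of patients arrives; the
   studied grid is 100–400 patients/month for the whole trial.
   Stand-alone trials are simulated as independent two-arm trials, each
   with its own accrual stream at the same mean.
2. **Randomization.** Each patient is assigned independently to one open
   arm with probability proportional to the allocation weights. Every drug
   arm has weight 1. The placebo weight is 1 (equal allocation), a fixed
   constant (the 1:1:1:1:2 MAT), or — under the dynamic rule of the
   `PT(1:1:1:1:k)` designs — the square root of the number `k` of drug
   arms currently enrolling, re-evaluated whenever an arm opens or closes.
   Square-root weighting is the allocation that maximizes per-comparison
   power for a given total: with four drugs enrolling the placebo weight
   is `sqrt(4) = 2`, and the placebo receives `1/(1 + sqrt(k))` of
   accrual. An arm closes the instant it reaches its cap (435 per drug;
   435 or 870 for capped placebos), so caps are hit exactly; a capped
   placebo is a planned enrollment group and completes its target even if
   the drug arms finish first, while the uncapped platform-trial placebo
   stops with the last drug arm.
3. **Arm entry.** All arms open at month 0 in stand-alone and multi-arm
   designs. In `PT` designs drug *i* (0-indexed) opens at month *i*; in
   `PT-irr` designs drug A opens at 0 and the others at i.i.d.
   Uniform(0, *m* − 1) times for *m* drugs (2, 3, 4 months for 3, 4, 5
   drugs), re-drawn each replicate. An arm entering at continuous time *t*
   first participates in the allocation of month `floor(t)` — with monthly
   accrual this is the natural convention, and it keeps arm 0 at month 0;
   rounding up instead would delay entries by under a month and slightly
   shrink the concurrent overlap.
4. **Outcomes.** Each patient dies independently with their arm's true
   mortality rate. The scenario grid crosses a placebo rate
   RP ∈ {5, 7.5, 10, 12.5, 15}% with an effective-drug rate RD = RP − 5
   points (so RD = 0 at RP = 5%), and effectiveness patterns in which
   scenario *s* makes the last *s* − 1 drugs effective; ineffective drugs
   sit at the placebo rate. For arm counts other than four we extend the
   same backwards-fill pattern, giving *m* + 1 scenarios for *m* drugs.
5. **Analysis.** Each drug is compared with its *concurrent controls*: the
   placebo patients enrolled between the drug's first and last enrollment
   months (inclusive). Simultaneous designs share one enrollment period by
   design, so there the whole placebo group is concurrent with every drug
   — 435 controls in the stand-alone and equal-MAT comparisons, 870 in the
   unequal MAT, exactly and in every replicate. The 2×2 death/survival
   table is tested by Pearson's chi-squared test without continuity
   correction; if any expected cell count is below 5 (Cochran's rule — the
   standard reading of "Fisher's exact test, if necessary") the two-sided
   Fisher exact test is used instead. Each drug is tested at two-sided 5%
   with no multiplicity adjustment, and a rejection in either direction
   counts: under the null that leaves the type I error at 5% rather than
   2.5%, and at a five-point mortality difference the wrong-direction
   contribution to power is far below Monte Carlo resolution.

### Sample size

The 435-per-arm cap is the classical normal-approximation two-proportion
sample size without continuity correction,

$$ n = \frac{\left(z_{\alpha/2}\sqrt{(1+1/r)\bar p\bar q} +
  z_\beta\sqrt{p_1 q_1 + p_2 q_2/r}\right)^2}{(p_1-p_2)^2}, $$

at $p_1 = 5\%$, $p_2 = 10\%$, two-sided $\alpha = 5\%$, 80% power and
$r = 1$, which gives 434.4 → 435 (`required_n_per_group(0.05, 0.10)`).
With the continuity correction the same inputs give ≈ 474, which is why
the test, the power formula, and the sample size all omit it consistently.
`approx_power()` is the matching analytic power
$\Phi\big((\delta - z_{\alpha/2}SE_0)/SE_1\big) +
 \Phi\big((-\delta - z_{\alpha/2}SE_0)/SE_1\big)$
(pooled $SE_0$, unpooled $SE_1$), used throughout the tests as an
independent cross-check on the simulator: it is strictly increasing in the
control-group size, which is the entire mechanism by which unequal
allocation to a shared placebo buys power.

### The dynamic allocation weight

The dynamic unequal rule is written `k:1` in the field's shorthand — the
shared placebo against weight-1 drug arms, with `k` the number of drug
groups currently enrolling. We implement the placebo weight as
$\sqrt{k}$, the square-root allocation rule, for two reasons. First, it is
the internally consistent reading of the benchmark designs: the
four-drug simultaneous unequal design uses placebo weight 2 = √4, not 4.
Second, it is the variant whose operating characteristics reproduce the
benchmark results across the board — group-specific power of the dynamic
four-drug platform trial at RP = 12.5% spanning ≈ 75–80% and *decreasing*
in the accrual rate, a total placebo count that *increases* with the
accrual rate, and per-drug concurrent-control counts that decrease with
it. A literal weight of `k` (placebo share 1/2 at all times) instead
yields 82–89% power and a flat total placebo count, qualitatively
incompatible with all three patterns. The literal-`k` variant remains
unavailable on purpose; `fixed_unequal` covers constant non-unit weights.

## Operating characteristics and their aggregation

`simulate_oc()` streams replicates — only the per-drug 2×2 ingredients,
placebo totals, and durations are retained, so 10,000-replicate runs need
no ledger storage (set `keep_decisions = TRUE` to keep the per-replicate
table). Every proportion is reported with its Monte Carlo standard error
$\sqrt{\hat p(1-\hat p)/n_{\text{reps}}}$. Group-specific power is the
per-drug rejection proportion among effective drugs and the type I error
rate the same among ineffective drugs; `avg_power`/`avg_tie` average over
the respective arm sets, since an arm contributes to exactly one of the
two in any scenario.

## The power-gain regression

For the platform-trial pair (dynamic vs equal allocation) simulated on the
same grid cell, `build_points()` records the difference in average
group-specific power (percentage points) and the difference in mean total
placebo patients. Cells with no effective drug carry no power, and cells
with RP = 5% are excluded by default: both designs sit at 100% power
there, so they carry no information about the gain. `fit_slope()` then
regresses the power difference on the placebo difference / 100, reporting
the gain in percentage points of average power per 100 additional placebo
patients with a normal-theory 95% interval.

Both an with-intercept and a through-origin fit are available. The
through-origin fit (`origin = TRUE`) is the specification behind the
headline per-100-patient rates: the placebo-size difference varies only
moderately across the grid (roughly 300–420 patients) while the power
difference varies strongly with RP at any given placebo difference, so a
free intercept leaves the slope poorly identified (wide interval, low
R²), whereas the zero-gain-at-zero-increase constraint — which is exact by
construction, as identical designs differ in nothing — pools the grid into
a tight per-100-patient rate. The with-intercept fit remains the default
in `fit_slope()` for exploratory use.

## Reproducibility and numerical choices

* **Seeding.** `run_oc_grid()` draws one sub-seed per grid cell from the
  master seed (`sample.int` under `set.seed(seed)`), so cells are
  reproducible and mutually independent, and paired designs within a cell
  use independent streams. `run_grid()` records the config snapshot and
  all cell seeds in a JSON manifest; identical configs reproduce the
  output CSVs byte for byte.
* **Exactness.** Sequential per-patient assignment with immediate arm
  closure makes every drug arm finish at exactly its cap and capped
  placebos at exactly theirs — the planned totals 3480 / 2175 / 2610 are
  invariants, not expectations. Within a month the engine draws the whole
  batch at once and re-draws past the first patient that would overflow an
  arm, which is distributionally identical to patient-by-patient
  assignment.
* **Outcome draws.** Deaths are drawn per (arm × month) cell from the
  matching binomial, which is distributionally identical to per-patient
  Bernoulli draws and lets a replicate run in microseconds; the
  ledger-level API (`assign_outcomes()`) draws per patient.
* **Degenerate tables.** A 2×2 with an empty death (or survival) margin
  routes to the Fisher branch via Cochran's rule and returns p = 1 — no
  decision either way rather than an error.
* **Randomization is independent per patient**, not block-permuted: the
  benchmark designs specify only ratios, and independent assignment
  handles mid-month closures and dynamic re-weighting naturally. Block
  randomization would shrink the (already tiny) within-month allocation
  noise but changes no operating characteristic at these sample sizes.

## Problem sizes used by the checks

The packaged tests run the full designs at reduced replicate counts:
10,000 replicates for single-design estimates (type I error, the
fixed-design power values), 2,000 per accrual mean for the dynamic-power
profile, and 2,000 per cell for the 64-cell (four-drug) and 48-cell
(three-drug) regression grids. The acceptance script uses 10,000 for
single-design estimates and 4,000 per regression cell. At these sizes a
simulated proportion carries a Monte Carlo standard error of at most
about 0.5 percentage points, and the regression slopes are stable to
about ±0.2.

A known limitation: the per-100-patient gain is not very sensitive to the
number of drug arms in this implementation. The three-drug platform
comparison simulates at a slightly *higher* per-100-patient rate than the
four-drug one (each extra placebo patient serves fewer comparisons, but
the per-drug windows capture a larger share of a smaller placebo pool),
rather than the markedly lower rate sometimes reported for three-arm
platforms; the acceptance script reports both slopes as simulated.

## What the generator does and does not emulate

The simulator reproduces the study conditions: Poisson accrual, immediate
outcome availability, independent Bernoulli mortality, and concurrent-only
analysis. It does not model outcome delay or follow-up windows, dropout,
calendar-time trends in mortality (the very reason concurrent controls
are used — under a time trend the non-concurrent comparison would be
biased, and that bias is outside what passing tests here demonstrate),
interim analyses, response-adaptive randomization, or survival endpoints.
Conclusions about those features of real platform trials cannot be drawn
from this package's green test suite.

## A worked example

```{r, eval = FALSE}
library(platformsim)

oc_k <- simulate_oc("PT(1:1:1:1:k)", scenario = 5, rp = 0.125,
                    accrual_mean = 100, n_reps = 10000, seed = 1)
oc_1 <- simulate_oc("PT(1:1:1:1:1)", scenario = 5, rp = 0.125,
                    accrual_mean = 100, n_reps = 10000, seed = 2)
glance(oc_k)
compare_designs(oc_k, oc_1)
autoplot(oc_k)

# the full power-gain regression (a few minutes)
grid <- run_oc_grid(c("PT(1:1:1:1:k)", "PT(1:1:1:1:1)"),
                    scenarios = 2:5, rps = c(0.075, 0.10, 0.125, 0.15),
                    accrual_means = c(100, 200, 300, 400),
                    n_reps = 4000, seed = 3)
fit <- fit_slope(build_points(grid, "PT(1:1:1:1:k)", "PT(1:1:1:1:1)"),
                 origin = TRUE)
glance(fit)
autoplot(fit)
```
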
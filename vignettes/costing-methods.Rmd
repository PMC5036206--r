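---
title: "Methods: lifetime inpatient costs by neighbourhood deprivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime inpatient costs by neighbourhood deprivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ineqcost)
```

# The problem and the model

England's inpatient activity is recorded as finished consultant episodes
(FCEs) carrying the patient's age, sex and small area of residence (LSOA,
~1 500 residents), plus a healthcare resource group (HRG) and length of
stay. Reimbursement follows the tariff attached to the HRG, with a per-diem
supplement for each bed day beyond the HRG's trim point. This package chains
five steps:

1. **Costing.** `cost_episodes()` computes
   `unit_cost + max(0, LOS - trim) * excess_per_diem` per episode, in exact
   integer pence. Deliberately *not* applied: the market forces factor (a
   local price adjustment) — the object of interest is variation in resource
   use, not in local prices.
2. **Exclusion and uplift.** Episodes missing age, sex or area cannot be
   placed in a demographic cell; `filter_groupable()` drops them and measures
   the missing fraction π. Group cost *totals* (never populations) are then
   multiplied by `1 + π`, under the assumption that missingness is equally
   distributed across patient groups and HRGs.
3. **Aggregation.** `aggregate_costs()` reduces to quintile × sex × single
   year of age (0–84, plus an open 85+ group) cells: episode counts, rates
   per 100 000 residents, and average annual cost per head
   c̄(g,a,s) = uplifted total / N(g,a,s).
4. **Cost of inequality.** `cost_of_inequality()` compares the observed cost
   with a direct-standardisation counterfactual: every quintile's population
   priced at the least-deprived quintile's age/sex-specific c̄. The gap is a
   pure difference — negative cells are reported, not floored — and the
   reference quintile's gap is zero by construction.
5. **Survival and lifetime costs.** `survival_from_counts()` builds a period
   life table per quintile and sex from banded death counts;
   `lifetime_costs()` weights c̄ by the probability of being alive,
   E(g,a,s) = S(g,a,s)·c̄(g,a,s), and accumulates L(g,s) = Σ_a E(g,a,s).

The lifetime projection assumes period rates: hospitalisation rates, costs
and mortality stay at their observed-year level, and an individual's
deprivation quintile is fixed for life. These are strong assumptions; they
make L(g,s) an interpretable summary of current conditions, not a forecast.

# Numerical and convention choices

Several conventions are genuinely open in this kind of analysis; the
defaults, and why:

* **Uplift `1 + π`, not `1/(1 − π)`.** The renormalisation `1/(1 − π)` is
  the unbiased correction for a fraction π of lost episodes; the literal
  percentage uplift is used as the standard presentation in this costing
  tradition. At π = 0.088 the two differ by ~0.8%; the choice is logged in
  every run (`run_log.yaml`).
* **Episode counts are never inflated** — only cost totals. Published
  whole-population episode tallies that mix pre- and post-exclusion counts
  cannot be reconciled without knowing how counts were scaled; the pipeline
  reports raw kept counts and leaves cost totals as the only uplifted
  quantity.
* **Quintiles are fifths of *areas*, not of population.** When the area
  count is not divisible by 5 the remainder goes to the more-deprived
  quintiles first, deterministically. Fifths of areas is the convention for
  IMD quintiles; population-weighted fifths would shift boundaries slightly.
* **`q = m` ("central" convention).** The banded central death rate is used
  directly as the annual death probability. The actuarial conversion
  `q = m/(1 + m/2)` is available via
  `life_table_options(q_convention = "actuarial")`; at adult rates the
  difference is second-order, at the open-age rate (~0.15) it reaches a few
  percent of q.
* **Band expansion is piecewise-constant.** Every single year in a 5-year
  band receives the band's rate; no graduation or smoothing is applied,
  since none is implied by banded inputs. The open 85+ rate is held constant
  to `max_age` (default 110) — the truncated source tables force the
  assumption that rates stop rising after 85, which biases old-age survival
  up and L with it.
* **Start-of-year survival weights.** E(a) = S(a)·c̄(a) uses the probability
  of being alive at the *start* of year a (the most literal reading of
  "alive to incur the cost"); `weighting = "midyear"` averages adjacent S
  values instead, which matters only where S falls quickly.
* **c̄ beyond age 84 is frozen at the 85+ value**, matching the population
  truncation.
* **Exact pence.** Costs are integer pence through aggregation (exact in
  doubles far below 2^53); the uplift and the division to per-head averages
  happen last. Observed and counterfactual quintile costs are computed from
  the *same* N·c̄ products, so the reference quintile's gap is exactly zero
  rather than zero up to floating-point reassociation.
* **Zero-population cells.** A populated cell with episodes but no residents
  is a hard error (the generator cannot produce one). A cell with residents
  in no year-of-age stratum has no observable c̄; in lifetime accumulation
  such ages contribute zero cost (`na_cost = "zero"`), a choice that only
  arises in small simulations where empty old-age cells are possible.

# The synthetic generator

Real episode-level extracts are access-restricted, so `simulate_dataset()`
produces a small-area world whose *statistical structure* matches what the
analysis assumes, with the generating parameters recorded as ground truth:

* **Areas and population.** `n_areas` areas (default 32 482) of
  `mean_area_pop` residents (default 1 500) with distinct deprivation ranks.
  Each quintile's age structure is the stationary population of the same
  Gompertz hazard used for its mortality — more-deprived areas are younger
  *because* their mortality is higher, keeping the two components internally
  consistent. Cell counts are Poisson.
* **Episodes.** Per-cell counts are Poisson with mean
  `N × age/sex baseline × quintile scalar`. The age baselines have a
  childhood peak, a dip near age 10 and exponential growth into old age,
  steeper for emergency admissions; female rates at ages 20–40 are multiplied
  by `female_repro_multiplier` (default 1.8) to emulate the reproductive-age
  spike. The default crude levels (0.198 elective, 0.115 emergency episodes
  per person-year in Q5) match published whole-population quintile rates.
* **Calibrated crude gradients.** The configured gradients (defaults Q1/Q5 =
  1.20 elective, 1.71 emergency, geometric interpolation between quintiles)
  are *crude-rate* ratios. Because quintiles differ in age structure, a
  na&iuml;ve scalar on age-specific rates would not yield the configured crude
  ratio; the generator therefore solves the quintile scalars against the
  realised population, so the expected crude ratio equals the configured
  value exactly and recovery tests are well-posed.
* **Mortality.** Deaths are binomial per single-year cell with
  `q = 1 - exp(-h)` under `h = gompertz_intercept × exp(gompertz_slope ×
  age)` (defaults 8×10⁻⁵ and 0.09 per year), scaled by the quintile hazard
  gradient (default Q1/Q5 = 1.5) and a female/male hazard ratio (default
  0.8), then aggregated to the 5-year bands of the national extracts. The
  open 85+ cell uses the survivor-weighted death probability over ages
  85–110.
* **Missingness.** Each episode is independently blanked with probability
  `missing_rate` (default 0.088, the published ungroupable fraction), losing
  one of age/sex/area uniformly — missingness is independent of cell, as the
  uplift assumes.
* **Tariffs.** Twenty pseudo-HRGs with gamma unit costs (mean £1 400),
  HRG-specific geometric lengths of stay, trim points and 5% per-diem
  supplements, so the excess-bed-day path is exercised. Twenty codes give
  enough heterogeneity to test the costing join without emulating the real
  ~1 400-HRG catalogue.
* **Seeding.** One master seed; each generator draws from a stream derived
  from a fixed label (`derive_seed()`), so adding a generator never perturbs
  existing outputs, and identical configs give byte-identical files.

**What the generator does not emulate:** clinical coding and the real HES
field set, within-year readmission correlation, over-dispersion in episode
counts (Poisson is assumed — no dispersion statement exists for the real
counts), infant-mortality excess (the Gompertz hazard is monotone from
birth), migration, and sex differences in admission rates beyond the
reproductive-age multiplier. The last point means the simulated female/male
lifetime cost ratio overstates what richer data show, where male admission
rates exceed female at older ages. Passing recovery tests therefore
demonstrate that the *pipeline* is correct under the stated data-generating
process, not that the process captures every feature of real admissions.

# Ground truth and test design

Every simulated dataset carries per-quintile expected episode counts, the
calibrated scalars, and expected pooled band death rates. Two subtleties:

* **Survival recovery** compares the estimated curve with the pipeline
  applied to *expected* band rates, not with the smooth Gompertz curve: the
  band-then-expand discretisation introduces a small bias that is not
  sampling error, and the recovery test should only absorb Monte-Carlo
  noise. Standard errors use the delta method on pooled binomial band rates.
* **Rate recovery** compares realised crude ratios with the configured
  targets using Poisson standard errors from the expected counts (missing
  records thin both quintiles equally, so the ratio is unaffected in
  expectation).

Independent oracles back the main formulas in the test suite: a
straight-line per-episode costing loop, closed forms for constant-hazard
survival and geometric-series lifetime costs, and a 200 000-life
micro-simulation for the survival-weighted lifetime accumulator.

Problem sizes: unit and property tests run on a shared 250-area × 800-person
world (~200 000 residents, ~70 000 episodes); the end-to-end recovery check
uses 2 000 areas × 1 500 residents (~3 million residents, ~1.1 million
episodes), enough for 3-standard-error recovery bounds on both gradients.

# Limitations

Beyond the generator's simplifications: the analysis does not adjust for
need or morbidity (it prices use as observed, making no judgement about
equity of access); outpatient and primary care are outside the costing —
the same pipeline runs on an outpatient-shaped episode file, but with
inpatient tariffs' semantics; confidence intervals for L(g,s) are not
produced; and area-level deprivation is an ecological proxy for individual
circumstances, which tends to attenuate gradients.
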
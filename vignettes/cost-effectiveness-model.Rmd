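---
title: "Methods: a Markov cost-effectiveness model of first-line EGFR-targeted therapy in advanced NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cost-effectiveness model of first-line EGFR-targeted therapy in advanced NSCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `nsclcCEA`: its structure
and assumptions, every tunable parameter and accounting convention, the
numerical choices, what the synthetic-data generators do and do not emulate,
and the model's known limitations. Nothing stated here goes beyond what the
package's tests and `scripts/acceptance.R` themselves compute.

## The decision problem

A cohort of Chinese patients with newly diagnosed stage IIIb/IV NSCLC
harbouring an activating EGFR mutation can receive one of four first-line
strategies: pemetrexed–cisplatin chemotherapy (PC, the control), PC followed
by pemetrexed maintenance, or gene-guided daily therapy with gefitinib or
icotinib. The question is which strategy buys health (QALYs) at an
acceptable price in a setting whose willingness-to-pay benchmark is 3× the
2015 per-capita GDP, $22,200 per QALY. All costs are 2015 US dollars; costs
and QALYs are discounted at 5% per year.

## Markov structure

Three mutually exclusive states: progression-free (PFS), post-progression,
dead. Everyone starts progression free. The cycle length is 21 days (one
chemotherapy cycle) and the horizon 10 years, i.e.
`floor(365·10/21) = 173` cycles, by which point state occupancy of the
alive states is numerically negligible.

* **PFS → post-progression.** PFS follows a Weibull model
  `S(t) = exp(−λ t^γ)` with the tabulated control-arm fit λ = 0.1029,
  γ = 1.3077. The per-cycle exit probability is
  `P(t) = 1 − exp(λ(t−1)^γ − λ t^γ)`, a telescoping form whose cumulative
  product reproduces `S(t)` exactly (asserted to 1e-12 in the tests). All
  PFS exits enter post-progression: the evidence base provides a PFS curve
  and a post-progression death rate, not a direct PFS→death rate, so
  overall survival is their composition.
* **Post-progression → dead.** Constant per-cycle death probability 0.086,
  which implies a median post-progression survival of
  `ln 2 / −ln(1−0.086) ≈ 7.7` cycles ≈ 5.3 months, matching the pooled
  estimate the probability was derived from.
* **Treatment effects.** Each alternative strategy multiplies the Weibull
  scale by its hazard ratio versus PC (λ' = λ·HR, shape unchanged) —
  the standard proportional-hazards adjustment. Note its quantitative
  force: mean PFS scales by `HR^(−1/γ)`, so HR = 0.40 *doubles* mean
  progression-free time (0.40^(−1/1.3077) ≈ 2.01).

## Evidence synthesis

Hazard ratios come from a frequentist random-effects network meta-analysis
of six trials on the log-HR scale. 95% CIs convert to standard errors as
`SE = (ln U − ln L)/3.92`. The network has five nodes — PC, pemetrexed
maintenance, non-pemetrexed platinum chemotherapy, gefitinib, icotinib —
and no loops: maintenance connects to PC directly; icotinib connects through
maintenance; the three gefitinib trials compare against non-pemetrexed
chemotherapy, which bridges to PC through a pemetrexed-vs-other-doublet
meta-analysis edge (HR 0.90). Estimation is inverse-variance weighted least
squares on the network design matrix with a single network-wide τ² from the
generalized DerSimonian–Laird moment estimator,
`df = n_studies − (n_nodes − 1) = 6 − 4 = 2`. In a loop-free network the
node estimates equal products of pooled edge HRs (asserted to 1e-10 against
that oracle), giving icotinib vs PC = 0.67 × 0.59 ≈ 0.395 → 0.40 at two
decimals. All residual heterogeneity lives on the gefitinib edge
(Q ≈ 5.85 on 2 df, I² ≈ 65.8%, vs the published 64.1% — the small gap is
estimator flavour: the source used a binomial-logit formulation). The
Markov engine takes its HRs from the parameter registry (the tabulated
pooled values 0.59/0.48/0.40) rather than from a live NMA fit, decoupling
cohort-model results from NMA numerics; `build_strategies(..., nma = )`
switches to live estimates.

## Parameters

`build_default_registry()` loads every tabulated quantity with base value,
one-way range and PSA distribution (`inst/extdata/parameters.yaml`).
Conventions:

* Ranges without a published value use ±25% of base.
* Gamma distributions are (shape, scale): shape·scale reproduces the
  tabulated cost means, which `validate_registry()` audits at a 2% relative
  tolerance. One published parameterization fails its own audit — the
  follow-up cost's gamma(437.5, 0.13) has mean 56.875 vs base 55.6 (2.3%
  off) — and is reported, not silently repaired; the base value is used in
  the base case.
* Hazard ratios are sampled from the published *normal* distributions
  truncated at zero (redraw on non-positive), as tabulated, even though the
  printed CIs look lognormal-asymmetric: the PSA follows the stated
  machinery. Probabilities and utilities sampled from normals (EGFR
  prevalence) are additionally redrawn above 1.
* The Weibull scale/shape carry no distribution and stay fixed in the PSA;
  survival uncertainty enters through the HR draws only.
* Salvage uptake (0.566, range 0.26–0.72) has a published range but no
  published distribution, so it is varied one-way but held fixed in the
  PSA rather than given an invented distribution.

## Costs and utilities

Per 21-day cycle, accrued on state occupancy and discounted:

* **Drugs.** PC induction: pemetrexed 500 mg/m² at BSA 1.72 m² = 860 mg,
  billed as two 500 mg vials (vial billing is standard practice;
  `vial_billing = FALSE` switches to exact milligrams) plus the $518.4
  chemotherapy backbone (cisplatin, administration, premedication) for four
  cycles. Maintenance continues single-agent pemetrexed until progression.
  TKIs cost price/day × 21 per cycle until progression (gefitinib $786.03,
  icotinib $666.12).
* **Patient-assistance program (PAP).** Caps cumulative per-patient TKI
  spend: full price through cycle `floor(cap/price)`, the remainder the
  following cycle, free thereafter (icotinib: 16 full cycles of $666.12,
  then $419.08, then $0 against the $11,077 cap).
* **Serious adverse events.** Cost per on-treatment PFS cycle =
  $507.4 × p(strategy)/p(control) using cumulative SAE probabilities;
  "on treatment" is induction-only for PC and all PFS cycles for
  maintenance/TKIs. The SAE disutility enters as a per-cycle QALY decrement
  `0.35 × p(strategy) × 21/365` over the same cycles.
* **After progression.** The salvage-uptake fraction receives salvage
  chemotherapy ($2,352.7/cycle) for the first 4 post-progression cycles
  (mirroring the first-line schedule length; `salvage_max_cycles` exposes
  it), supportive care ($337.5/cycle) otherwise; terminal care ($2,042.91)
  is a one-off on each death.
* **EGFR testing.** Gene-guided strategies carry an up-front
  $380.95/0.47 ≈ $811 per treated (mutation-positive) patient — the test
  cost amortized over the mutation prevalence, which is why prevalence is a
  sensitivity variable although the simulated cohort is 100% positive.
* **Follow-up.** $55.6 per cycle while alive; the billing unit is not
  defined by the source ("per unit"), so it is a flag (`followup_unit`).
* Utilities 0.82 (PFS) and 0.58 (post-progression); life years are
  reported undiscounted, QALYs and costs discounted per cycle start,
  `(1.05)^(−cycle·21/365)`.

## Accounting conventions and their calibration

The published analysis leaves several conventions unstated, and its printed
base-case table is not mutually consistent: its control row implies
QALYs = 0.82×0.206 + 0.58×0.852 = 0.663 against a printed 0.513, and its
PF-LY ratio between icotinib and control (0.303/0.206 = 1.47) is
incompatible with the stated λ·HR adjustment (which forces
0.40^(−1/1.3077) = 2.01). No convention choice can reproduce that table
from the stated inputs.

The engine therefore exposes every open convention as a flag — Weibull time
unit (`cycle`/`month`), salvage duration, follow-up billing unit, SAE
disutility treatment, half-cycle correction, induction billing
(`occupancy`: drugs billed to the progression-free fraction; `committed`:
the full four-cycle induction course billed to the alive cohort, reflecting
per-protocol delivery) — and `analysis/02_convention_calibration.R` scans
the full 64-combination grid against the *control row only* (alternative
strategies never enter). The life-year and QALY cells are invariant to
every flag (they are fixed by the Weibull parameters and cycle structure),
so the cost cell decides. The frozen set, exported as
`calibrated_config()`: cycle time unit, 4 salvage cycles, per-cycle
follow-up, on-treatment SAE disutility, half-cycle correction on, committed
induction billing. `model_config()` keeps neutral defaults (half-cycle off,
occupancy billing) for users who want the conventional textbook settings.

What the frozen model reproduces and what it does not (all recomputed by
the tests and acceptance script, never asserted from memory):

* control-strategy discounted cost within 2% of the published $22,127;
* network I² within 2 points of the published 64.1%, pooled icotinib HR
  0.40 exactly at two decimals;
* the dominance structure: pemetrexed maintenance and gefitinib simply
  dominated, icotinib undominated with the most QALYs; PAP caps lower both
  TKI strategies' costs;
* **not** the published positive incremental costs and ICERs: under the
  stated prices and the stated survival machinery, the TKIs are
  cost-saving versus PC (icotinib ΔC ≈ −$2,500, ΔQALY ≈ +0.25), because
  HR = 0.40 doubles the progression-free period while the daily TKI price
  keeps the drug bill below the induction chemotherapy bill. The published
  ICERs (19,809–104,657 $/QALY) require a far weaker effect of the HR on
  accrued QALYs (Δ ≈ 0.094) than the stated model produces; for the same
  reason the one-way ranking here puts the icotinib HR and price among the
  widest tornado bars, where the source reports pemetrexed cost, EGFR
  prevalence and PFS utility on top with only a moderate HR effect, and the
  probabilistic acceptability of icotinib at $22,200/QALY comes out near
  98% rather than the published ≈90% — dominance in most draws, not merely
  acceptable cost per QALY.

## Sensitivity analyses

* **One-way.** Every registry entry flagged as varied (all tabulated
  clinical, cost and utility parameters plus salvage uptake; not the
  structural entries — Weibull parameters, discount rate, threshold, PAP
  caps) is set to its bounds with everything else at base; the pairwise
  ICER is recomputed and entries ranked by spread. Non-finite ICERs at a
  bound (possible when ΔQALY crosses zero) are flagged, not dropped.
* **Probabilistic.** 1,000 draws; all strategies evaluated on the same
  draw; seeded and reproducible. Acceptability at threshold λ is the
  fraction of draws in which a strategy's net monetary benefit
  `λ·QALY − cost` is maximal, exact ties split equally (a measure-zero
  event under continuous draws, but defined so degenerate tests behave).
  The default grid is $0–60,000 in $500 steps; the analysis driver adds
  the exact $22,200 line.

## Synthetic data

Two generators make every stage testable without external data, and state
what they do *not* emulate:

* `gen_km_curve()` draws Weibull event times with independent exponential
  censoring and returns the Kaplan–Meier product-limit estimate (via the
  `survival` package). It emulates the statistical structure the log-log
  least-squares fitter assumes — not the published control-arm curve's
  digitization artefacts, risk-table granularity or informative-censoring
  patterns. Parameter recovery on n = 500 noisy curves is within 10%;
  noiseless curves are recovered exactly (r² = 1 on the linearized scale).
* `gen_nma_trials()` builds trials as true edge effect + Normal(0, τ²)
  study effect + Normal(0, SE²) sampling error, reported as HR with 95% CI.
  It validates pooling calibration (DL τ̂² within 25% of truth over 1,000
  replicates; ~95% CI coverage) but does not emulate small-study bias,
  correlated multi-arm trials or non-normal effect distributions.

Passing these tests therefore shows the estimators are correct under their
own assumptions; it does not validate the Weibull family or the
proportional-hazards transfer against real trial data.

## Numerical choices

* Weibull fitting uses the linearized least-squares estimator
  `ln(−ln S) = ln λ + γ ln t` (not MLE) because it naturally yields the r²
  statistic used to describe fit quality; points with S ∈ {0, 1} or t = 0
  are excluded as the transform is undefined there; at least 3 usable
  points are required.
* DL τ² truncates at 0; I² = max(0, (Q − df)/Q)·100.
* Truncated-normal sampling retries up to 1,000 times before erroring.
* Occupancy conservation is asserted inside the engine at 1e-9 on every
  run (tests check 1e-12); cohort arithmetic is plain double precision.
* Problem sizes: 173-cycle cohort runs take milliseconds; the 1,000-draw
  PSA runs in seconds; replicate counts in the property tests (1,000) were
  chosen for comfortable Monte-Carlo error, not shaved for speed.

## Limitations

* The model inherits every simplification of its source: no
  treatment-switching or second-line TKI modelling beyond a priced salvage
  bundle, no tolerability modelling beyond the SAE cost/disutility terms,
  no direct PFS→death transitions, utilities not specific to the Chinese
  population.
* The published base-case table cannot be reproduced from the published
  inputs (see above); this package chooses transparency — faithful
  machinery, frozen documented conventions, honest divergence — over
  matching printed numbers.
* The frequentist WLS network meta-analysis approximates the published
  binomial-logit analysis; pooled gefitinib differs by ~0.02 in HR.
* No EVPI, budget-impact, or plotting layer; outputs are CSV-ready tables.
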
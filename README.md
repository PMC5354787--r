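# nsclcCEA

Decision-analytic cost-effectiveness model for first-line treatment of
EGFR-mutation-positive advanced non-small cell lung cancer (NSCLC) in the
Chinese health-care setting. Four competing strategies are compared:

1. **PC** — pemetrexed (500 mg/m²) plus cisplatin, four 21-day induction
   cycles (control);
2. **Pemetrexed maintenance** — PC induction followed by single-agent
   pemetrexed until progression;
3. **Gefitinib** — 250 mg/day until progression, after EGFR testing;
4. **Icotinib** — 375 mg/day until progression, after EGFR testing.

The package is written for health-economics researchers who want every stage
of such an analysis — evidence synthesis, survival extrapolation, cohort
simulation, incremental and sensitivity analysis — as tested, reusable
functions rather than a spreadsheet.

## Model core

* **Progression-free survival** follows a Weibull model
  `S(t) = exp(−λ t^γ)` with λ = 0.1029 and γ = 1.3077 (t in 21-day cycles),
  fitted to the control arm of the maintenance trial. Per-cycle transition
  probabilities are `P(t) = 1 − exp(λ(t−1)^γ − λ t^γ)`, so that
  `∏(1 − P(k)) = S(t)` exactly. Alternative strategies scale the hazard:
  `λ' = λ · HR`.
* **Hazard ratios** come from a frequentist random-effects network
  meta-analysis on the log-HR scale (inverse-variance weighted least squares
  on the network design matrix, generalized DerSimonian–Laird τ²) over six
  trials connecting PC, pemetrexed maintenance, non-pemetrexed chemotherapy,
  gefitinib and icotinib. The network is loop-free, so node estimates equal
  products of pooled edge hazard ratios (icotinib vs PC: 0.67 × 0.59 ≈ 0.40).
* **Markov cohort engine**: three states (progression-free, post-progression,
  dead), 21-day cycles, 10-year horizon (173 cycles), 5%/year discounting.
  Post-progression patients die with per-cycle probability 0.086; cost and
  QALY accrual covers drugs (with patient-assistance-program caps), serious
  adverse events, follow-up, salvage and supportive care, terminal care and
  EGFR-test amortization (test cost ÷ mutation prevalence).
* **Decision analysis**: pairwise ICERs versus PC with frontier dominance
  labels; one-way (tornado) sensitivity over every parameter range;
  1,000-draw probabilistic sensitivity analysis (beta / gamma / truncated
  normal distributions) and cost-effectiveness acceptability curves from net
  monetary benefit `λ·QALY − cost` at a willingness-to-pay threshold of
  $22,200/QALY (3× 2015 Chinese per-capita GDP).

## Worked example

```r
library(nsclcCEA)

reg  <- build_default_registry()          # all tabulated parameters
pars <- base_values(reg)
cfg  <- calibrated_config()               # frozen accounting conventions

nma_estimate(read_trial_effects())
#> <nma_result> reference = pc; Q = 5.853 on 2 df; tau2 = 0.0528; I2 = 65.8%

rs  <- run_strategy_set(build_strategies(pars, cfg), pars, cfg)
incremental_analysis(rs, reference = "pc")
```

gives (costs in 2015 US$, discounted; QALYs discounted; LYs undiscounted):

| strategy | cost | PF-LYs | LYs | QALYs | ΔC vs PC | ΔQALY | ICER | label |
|---|---|---|---|---|---|---|---|---|
| pc | 21,731 | 0.302 | 0.971 | 0.588 | — | — | — | reference |
| pemetrexed_maintenance | 34,154 | 0.452 | 1.121 | 0.634 | +12,422 | 0.046 | 269,923 | simple_dominated |
| gefitinib | 19,564 | 0.530 | 1.199 | 0.775 | −2,168 | 0.187 | −11,606 | simple_dominated |
| icotinib | 19,196 | 0.609 | 1.278 | 0.840 | −2,536 | 0.251 | −10,094 | on_frontier |

Icotinib yields the most QALYs and is cost-saving against PC: at $31.72/day
its drug bill over the (doubled) progression-free period stays below the
four-cycle pemetrexed-cisplatin induction bill, while maintenance and
gefitinib are simply dominated. Negative ICERs here mean "more QALYs for
less money". With the patient-assistance caps (`pap = TRUE`) the TKI costs
fall further (icotinib: $18,319). In the probabilistic analysis icotinib has
the highest net monetary benefit at $22,200/QALY in ~98% of 1,000 draws.

The numbered drivers under `analysis/` run the whole study and write their
tables to `results/`:

```sh
Rscript analysis/01_evidence_synthesis.R      # NMA: pooled HRs, I²
Rscript analysis/02_convention_calibration.R  # convention-flag calibration
Rscript analysis/03_base_case.R               # base-case summary table
Rscript analysis/04_tornado.R                 # one-way sensitivity
Rscript analysis/05_psa_ceac.R                # PSA + acceptability curves
```

The published base-case table this model re-derives is internally
inconsistent with its own stated inputs (its control-row QALYs are
incompatible with its own utilities and life-year split, and its printed
PF-LY ratios are incompatible with the stated `λ·HR` adjustment), so the
accounting conventions were calibrated against the control row only and
frozen (`calibrated_config()`); the methods vignette
(`vignettes/cost-effectiveness-model.Rmd`) documents every convention,
the calibration, and which published quantities the model does and does not
reproduce.

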
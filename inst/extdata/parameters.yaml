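# Model parameter registry: base-case values, one-way ranges and PSA
# distributions for the first-line EGFR-mutant NSCLC cost-effectiveness model.
# All costs are 2015 US dollars.  dist families: beta(p1 = alpha, p2 = beta),
# gamma(p1 = shape, p2 = scale), normal(p1 = mean, p2 = sd).
# vary: entry is varied in the one-way (tornado) sensitivity analysis.
# kind guides sampling guards (probability/utility draws must stay in [0,1]).
- name: weibull_scale
  base: 0.1029
  low: 0.077175
  high: 0.128625
  units: per cycle^shape
  kind: other
  vary: no
  source: PFS Weibull fit, control arm
- name: weibull_shape
  base: 1.3077
  low: 0.980775
  high: 1.634625
  units: dimensionless
  kind: other
  vary: no
  source: PFS Weibull fit, control arm
- name: hr_maintenance
  base: 0.59
  low: 0.4425
  high: 0.7375
  dist: {family: normal, p1: 0.59, p2: 0.161}
  units: hazard ratio vs PC
  kind: ratio
  vary: yes
  source: network meta-analysis
- name: hr_gefitinib
  base: 0.48
  low: 0.29
  high: 0.80
  dist: {family: normal, p1: 0.48, p2: 0.13}
  units: hazard ratio vs PC
  kind: ratio
  vary: yes
  source: network meta-analysis
- name: hr_icotinib
  base: 0.40
  low: 0.19
  high: 0.81
  dist: {family: normal, p1: 0.40, p2: 0.158}
  units: hazard ratio vs PC
  kind: ratio
  vary: yes
  source: network meta-analysis
- name: prob_pps_death
  base: 0.086
  low: 0.08
  high: 0.093
  dist: {family: beta, p1: 751.1, p2: 7982.7}
  units: probability per 21-day cycle
  kind: probability
  vary: yes
  source: pooled post-progression survival
- name: egfr_prevalence
  base: 0.47
  low: 0.20
  high: 0.76
  dist: {family: normal, p1: 0.47, p2: 0.143}
  units: proportion
  kind: probability
  vary: yes
  source: Asia-Pacific EGFR mutation frequency
- name: prob_sae_control
  base: 0.456
  low: 0.342
  high: 0.57
  dist: {family: beta, p1: 33.6, p2: 40.1}
  units: cumulative probability
  kind: probability
  vary: yes
  source: PC chemotherapy trials
- name: prob_sae_maintenance
  base: 0.637
  low: 0.478
  high: 0.796
  dist: {family: beta, p1: 22.4, p2: 12.8}
  units: cumulative probability
  kind: probability
  vary: yes
  source: pemetrexed maintenance trial
- name: prob_sae_gefitinib
  base: 0.1
  low: 0.075
  high: 0.125
  dist: {family: beta, p1: 53.3, p2: 479.3}
  units: cumulative probability
  kind: probability
  vary: yes
  source: gefitinib trials
- name: prob_sae_icotinib
  base: 0.07
  low: 0.053
  high: 0.088
  dist: {family: beta, p1: 56.3, p2: 747.4}
  units: cumulative probability
  kind: probability
  vary: yes
  source: icotinib trials
- name: body_surface_area
  base: 1.72
  low: 1.5
  high: 1.9
  dist: {family: normal, p1: 1.72, p2: 0.102}
  units: m^2
  kind: other
  vary: yes
  source: typical patient 65 kg / 1.64 m
- name: cost_pemetrexed_500mg
  base: 967.57
  low: 533.02
  high: 2126.51
  dist: {family: gamma, p1: 2303, p2: 0.42}
  units: USD per 500 mg vial
  kind: cost
  vary: yes
  source: generic pemetrexed price
- name: cost_chemo_backbone_cycle
  base: 518.4
  low: 388.8
  high: 648
  dist: {family: gamma, p1: 4064.3, p2: 0.13}
  units: USD per 21-day cycle
  kind: cost
  vary: yes
  source: chemotherapy excluding non-platinum agents
- name: cost_icotinib_day
  base: 31.72
  low: 15.86
  high: 31.72
  dist: {family: gamma, p1: 248.7, p2: 0.13}
  units: USD per day
  kind: cost
  vary: yes
  source: local charge
- name: cost_gefitinib_day
  base: 37.43
  low: 18.71
  high: 37.43
  dist: {family: gamma, p1: 293.4, p2: 0.13}
  units: USD per day
  kind: cost
  vary: yes
  source: local charge
- name: cost_followup_unit
  base: 55.6
  low: 41.7
  high: 69.4
  dist: {family: gamma, p1: 437.5, p2: 0.13}
  units: USD per follow-up unit
  kind: cost
  vary: yes
  source: routine follow-up and laboratory testing
- name: cost_salvage_cycle
  base: 2352.7
  low: 1921.1
  high: 4383.3
  dist: {family: gamma, p1: 8812.4, p2: 0.27}
  units: USD per cycle
  kind: cost
  vary: yes
  source: salvage chemotherapy
- name: cost_terminal_care
  base: 2042.91
  low: 793.65
  high: 5456.19
  dist: {family: gamma, p1: 3508.8, p2: 0.58}
  units: USD one-off
  kind: cost
  vary: yes
  source: palliative end-of-life care
- name: cost_supportive_cycle
  base: 337.5
  low: 158.7
  high: 793.7
  dist: {family: gamma, p1: 703.2, p2: 0.48}
  units: USD per cycle
  kind: cost
  vary: yes
  source: supportive care
- name: cost_sae_unit
  base: 507.4
  low: 189.7
  high: 825.0
  dist: {family: gamma, p1: 1588.6, p2: 0.32}
  units: USD per on-treatment cycle (control)
  kind: cost
  vary: yes
  source: SAE management
- name: cost_egfr_test
  base: 380.95
  low: 158.73
  high: 476.19
  dist: {family: gamma, p1: 1792, p2: 0.21}
  units: USD per test
  kind: cost
  vary: yes
  source: local laboratory charge
- name: utility_pfs
  base: 0.82
  low: 0.78
  high: 0.86
  dist: {family: beta, p1: 373.6, p2: 82}
  units: utility weight
  kind: utility
  vary: yes
  source: published utilities
- name: utility_pps
  base: 0.58
  low: 0.50
  high: 0.66
  dist: {family: beta, p1: 84, p2: 60.9}
  units: utility weight
  kind: utility
  vary: yes
  source: published utilities
- name: disutility_sae
  base: 0.35
  low: 0.31
  high: 0.39
  dist: {family: beta, p1: 199.1, p2: 369.7}
  units: utility decrement
  kind: utility
  vary: yes
  source: published disutilities
- name: salvage_uptake
  base: 0.566
  low: 0.26
  high: 0.72
  units: proportion
  kind: probability
  vary: yes
  source: proportion receiving salvage treatment
- name: discount_annual
  base: 0.05
  low: 0.0375
  high: 0.0625
  units: per year
  kind: other
  vary: no
  source: Chinese pharmacoeconomic guidelines
- name: wtp_threshold
  base: 22200
  low: 16650
  high: 27750
  units: USD per QALY
  kind: other
  vary: no
  source: 3x Chinese per-capita GDP, 2015
- name: pap_cap_gefitinib
  base: 11538
  low: 8653.5
  high: 14422.5
  units: USD per patient
  kind: cost
  vary: no
  source: patient assistance program
- name: pap_cap_icotinib
  base: 11077
  low: 8307.75
  high: 13846.25
  units: USD per patient
  kind: cost
  vary: no
  source: patient assistance program
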
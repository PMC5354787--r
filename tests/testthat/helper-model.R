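# shared fixtures: registry, base parameters and a short-horizon config so
# unit tests stay fast
the_registry <- build_default_registry()
the_pars <- base_values(the_registry)

short_config <- function(...) model_config(horizon_years = 1, ...)

# single-distribution draw (internal sampler) for moment/KS checks
draw_one_for_test <- function(dist, kind) nsclcCEA:::draw_one(dist, kind)

# independent spreadsheet-style unrolling of the control strategy over a
# few cycles, written against the model's accounting rules but without the
# engine's state machinery (no salvage ageing shortcuts: explicit per-entry
# bookkeeping); oracle for run_cohort()
unroll_control <- function(pars, n_cycles, salvage_max = 4) {
  lam <- pars[["weibull_scale"]]; gam <- pars[["weibull_shape"]]
  pd <- pars[["prob_pps_death"]]
  S <- exp(-lam * (0:n_cycles)^gam)
  cy <- 21 / 365
  disc <- (1.05)^(-(0:(n_cycles - 1)) * cy)
  # pp cohort ledger: entries[k] = fraction that progressed at end of cycle k
  entrants <- numeric(n_cycles)
  cost <- qaly <- 0
  pem <- ceiling(pars[["body_surface_area"]]) * pars[["cost_pemetrexed_500mg"]]
  drug_cycle <- pem + pars[["cost_chemo_backbone_cycle"]]
  for (t in 1:n_cycles) {
    pfs_start <- S[t]
    # post-progression occupancy by age at start of cycle t
    pp_by_age <- if (t > 1) {
      ages <- (t - 1):1
      entrants[1:(t - 1)] * (1 - pd)^(ages - 1)
    } else numeric(0)
    pp_start <- sum(pp_by_age)
    dead_start <- 1 - pfs_start - pp_start
    new_deaths <- pp_start * pd
    entrants[t] <- S[t] - S[t + 1]
    c_drug <- if (t <= 4) drug_cycle * pfs_start else 0
    c_sae <- if (t <= 4) pars[["cost_sae_unit"]] * pfs_start else 0
    c_fu <- pars[["cost_followup_unit"]] * (pfs_start + pp_start)
    ages <- if (t > 1) ((t - 1):1) else integer(0)
    salv_occ <- sum(pp_by_age[ages <= salvage_max])
    c_salv <- pars[["cost_salvage_cycle"]] * pars[["salvage_uptake"]] * salv_occ
    c_supp <- pars[["cost_supportive_cycle"]] *
      (pp_start - pars[["salvage_uptake"]] * salv_occ)
    c_term <- pars[["cost_terminal_care"]] * new_deaths
    cost <- cost + disc[t] * (c_drug + c_sae + c_fu + c_salv + c_supp + c_term)
    du <- if (t <= 4) pars[["disutility_sae"]] * pars[["prob_sae_control"]] * pfs_start else 0
    qaly <- qaly + disc[t] * cy *
      (pfs_start * pars[["utility_pfs"]] + pp_start * pars[["utility_pps"]] - du)
  }
  list(cost = cost, qalys = qaly)
}
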
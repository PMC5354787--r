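#' Markov model configuration
#'
#' Structural settings and accounting conventions of the cohort engine.
#' The defaults are the model's frozen conventions (see the methods
#' vignette for the rationale behind each choice); every convention the
#' source tables leave open is exposed as a flag.
#'
#' @param cycle_days Cycle length in days (21).
#' @param horizon_years Time horizon in years (10); the number of cycles is
#'   `floor(365 * horizon_years / cycle_days)` = 173 at the defaults.
#' @param discount_annual Annual discount rate for costs and QALYs (0.05).
#' @param half_cycle Logical; accrue on the mean of start- and end-of-cycle
#'   occupancy instead of start-of-cycle occupancy.
#' @param salvage_max_cycles Cycles of salvage chemotherapy offered after
#'   progression (to the salvage-uptake fraction) before switching to
#'   supportive care.
#' @param time_unit Unit in which the Weibull PFS clock advances per model
#'   cycle: `"cycle"` (the cycle index itself) or `"month"` (each 21-day
#'   cycle advances the clock by 21/30.4375 months).
#' @param sae_disutility `"on_treatment"` (per-cycle QALY decrement
#'   `disutility * sae_prob * cycle_years` during on-treatment PFS cycles)
#'   or `"none"`.
#' @param followup_unit Billing unit of the follow-up cost: `"cycle"`
#'   (charged once per 21-day cycle while alive) or `"month"`.
#' @param induction_billing `"occupancy"` (induction drugs billed to the
#'   progression-free fraction each induction cycle) or `"committed"` (the
#'   full induction course is billed to the alive fraction, reflecting
#'   per-protocol delivery of all induction cycles).
#' @param vial_billing Logical; pemetrexed billed as whole 500 mg vials
#'   rounded up (default) or as exact milligrams.
#' @param wtp_threshold Willingness-to-pay threshold, $/QALY.
#' @return List of class `cea_config`.
#' @export
model_config <- function(cycle_days = 21,
                         horizon_years = 10,
                         discount_annual = 0.05,
                         half_cycle = FALSE,
                         salvage_max_cycles = 4,
                         time_unit = c("cycle", "month"),
                         sae_disutility = c("on_treatment", "none"),
                         followup_unit = c("cycle", "month"),
                         induction_billing = c("occupancy", "committed"),
                         vial_billing = TRUE,
                         wtp_threshold = 22200) {
  cfg <- list(
    cycle_days = cycle_days,
    horizon_years = horizon_years,
    discount_annual = discount_annual,
    half_cycle = isTRUE(half_cycle),
    salvage_max_cycles = as.integer(salvage_max_cycles),
    time_unit = match.arg(time_unit),
    sae_disutility = match.arg(sae_disutility),
    followup_unit = match.arg(followup_unit),
    induction_billing = match.arg(induction_billing),
    vial_billing = isTRUE(vial_billing),
    wtp_threshold = wtp_threshold
  )
  stopifnot(cfg$cycle_days > 0, cfg$horizon_years > 0,
            cfg$discount_annual >= 0, cfg$salvage_max_cycles >= 0)
  cfg$n_cycles <- as.integer(floor(365 * cfg$horizon_years / cfg$cycle_days))
  class(cfg) <- "cea_config"
  cfg
}

#' Discount factor at a model cycle
#'
#' `(1 + discount_annual)^(-cycle * cycle_days / 365)`; cycle 0 is
#' undiscounted.
#'
#' @param cfg A `cea_config`.
#' @param cycle Cycle index (0-based), vectorized.
#' @return Discount factor(s) in (0, 1].
#' @export
discount_factor <- function(cfg, cycle) {
  if (any(cycle < 0)) stop("cycle index must be non-negative")
  (1 + cfg$discount_annual)^(-cycle * cfg$cycle_days / 365)
}

#' Per-cycle cost of serious-adverse-event management for a strategy
#'
#' SAE management is priced as the control strategy's per-cycle SAE cost
#' scaled by the ratio of cumulative SAE probabilities:
#' `cost_sae_unit * sae_prob(strategy) / sae_prob(control)`.
#'
#' @param pars Named parameter vector (see [base_values()]).
#' @param sae_prob Cumulative SAE probability of the strategy.
#' @return Per on-treatment-cycle SAE cost, $.
#' @export
sae_cost_per_cycle <- function(pars, sae_prob) {
  p0 <- pars[["prob_sae_control"]]
  if (p0 <= 0) stop("control SAE probability must be positive")
  pars[["cost_sae_unit"]] * sae_prob / p0
}

# per-cycle cost of one pemetrexed dose (500 mg/m2) at the current price
pemetrexed_dose_cost <- function(pars, cfg) {
  dose_mg <- 500 * pars[["body_surface_area"]]
  if (cfg$vial_billing) {
    ceiling(dose_mg / 500) * pars[["cost_pemetrexed_500mg"]]
  } else {
    dose_mg / 500 * pars[["cost_pemetrexed_500mg"]]
  }
}

#' Build the four competing treatment strategies
#'
#' Constructs the strategy specifications consumed by [run_cohort()]:
#' \describe{
#'   \item{pc}{Pemetrexed-cisplatin chemotherapy, 4 induction cycles, no
#'     further first-line drug (control; hazard ratio 1).}
#'   \item{pemetrexed_maintenance}{4 PC induction cycles then single-agent
#'     pemetrexed each cycle until progression.}
#'   \item{gefitinib}{Daily gefitinib until progression; EGFR testing.}
#'   \item{icotinib}{Daily icotinib until progression; EGFR testing.}
#' }
#' Hazard ratios default to the registry values (the pooled network
#' meta-analysis estimates); pass an `nma_result` to use freshly fitted
#' values instead.
#'
#' @param pars Named parameter vector (base case: `base_values(reg)`; a PSA
#'   draw: [sample_parameters()]).
#' @param cfg A `cea_config`.
#' @param pap Logical; attach the patient-assistance-program drug-cost caps
#'   to the TKI strategies.
#' @param nma Optional `nma_result`; when supplied, maintenance/gefitinib/
#'   icotinib hazard ratios are taken from its pooled estimates (nodes
#'   `pemetrexed_maintenance`, `gefitinib`, `icotinib` vs reference).
#' @return Named list of `cea_strategy` objects.
#' @export
build_strategies <- function(pars, cfg = model_config(), pap = FALSE, nma = NULL) {
  need <- c("hr_maintenance", "hr_gefitinib", "hr_icotinib",
            "cost_pemetrexed_500mg", "cost_chemo_backbone_cycle",
            "cost_icotinib_day", "cost_gefitinib_day",
            "prob_sae_control", "prob_sae_maintenance",
            "prob_sae_gefitinib", "prob_sae_icotinib",
            "body_surface_area", "pap_cap_gefitinib", "pap_cap_icotinib")
  missing <- setdiff(need, names(pars))
  if (length(missing)) stop("parameter vector missing entries: ",
                            paste(missing, collapse = ", "))
  hrs <- if (is.null(nma)) {
    c(maintenance = pars[["hr_maintenance"]],
      gefitinib = pars[["hr_gefitinib"]],
      icotinib = pars[["hr_icotinib"]])
  } else {
    c(maintenance = nma_hr(nma, "pemetrexed_maintenance"),
      gefitinib = nma_hr(nma, "gefitinib"),
      icotinib = nma_hr(nma, "icotinib"))
  }
  pem <- pemetrexed_dose_cost(pars, cfg)
  chemo_cycle <- pem + pars[["cost_chemo_backbone_cycle"]]
  strat <- function(name, hr, induction_cycles, induction_cost,
                    continuation_cost, sae_prob, on_treatment,
                    egfr_test, pap_cap) {
    structure(list(name = name, hr = hr,
                   induction_cycles = induction_cycles,
                   induction_cost = induction_cost,
                   continuation_cost = continuation_cost,
                   sae_prob = sae_prob, on_treatment = on_treatment,
                   egfr_test = egfr_test, pap_cap = pap_cap),
              class = "cea_strategy")
  }
  list(
    pc = strat("pc", 1, 4L, chemo_cycle, 0,
               pars[["prob_sae_control"]], "induction", FALSE, NA_real_),
    pemetrexed_maintenance = strat("pemetrexed_maintenance",
               hrs[["maintenance"]], 4L, chemo_cycle, pem,
               pars[["prob_sae_maintenance"]], "pfs", FALSE, NA_real_),
    gefitinib = strat("gefitinib", hrs[["gefitinib"]], 0L, 0,
               pars[["cost_gefitinib_day"]] * cfg$cycle_days,
               pars[["prob_sae_gefitinib"]], "pfs", TRUE,
               if (pap) pars[["pap_cap_gefitinib"]] else NA_real_),
    icotinib = strat("icotinib", hrs[["icotinib"]], 0L, 0,
               pars[["cost_icotinib_day"]] * cfg$cycle_days,
               pars[["prob_sae_icotinib"]], "pfs", TRUE,
               if (pap) pars[["pap_cap_icotinib"]] else NA_real_)
  )
}

#' Per-cycle drug cost schedule under a patient-assistance-program cap
#'
#' The PAP truncates each patient's cumulative TKI spend at the cap: the
#' full per-cycle cost is billed through cycle `floor(cap / cost)`, the
#' remainder in the following cycle, zero thereafter.
#'
#' @param cost_per_cycle Uncapped per-cycle drug cost.
#' @param cap Per-patient cap, $ (must be positive; `Inf` disables the cap).
#' @param n_cycles Number of cycles to schedule.
#' @return Numeric vector of per-cycle unit drug costs, length `n_cycles`.
#' @export
apply_pap_cap <- function(cost_per_cycle, cap, n_cycles) {
  if (is.na(cap)) cap <- Inf
  if (cap <= 0) stop("PAP cap must be positive")
  if (cost_per_cycle <= 0 || !is.finite(cap)) {
    return(rep(cost_per_cycle, n_cycles))
  }
  full <- floor(cap / cost_per_cycle)
  sched <- numeric(n_cycles)
  sched[seq_len(min(full, n_cycles))] <- cost_per_cycle
  if (full < n_cycles) sched[full + 1] <- cap - full * cost_per_cycle
  sched
}

#' Run the three-state cohort model for one strategy
#'
#' Simulates a cohort starting 100% progression free through
#' `cfg$n_cycles` cycles of length `cfg$cycle_days`.  Exits from PFS follow
#' the strategy's hazard-ratio-adjusted Weibull transition probabilities
#' (all exits enter the post-progression state); post-progression patients
#' die with a constant per-cycle probability (`prob_pps_death`).  Cost and
#' QALY accrual per cycle:
#' \itemize{
#'   \item PFS: scheduled drug cost (PAP-capped for TKIs), SAE management
#'     cost during on-treatment cycles, utility `utility_pfs` minus the SAE
#'     disutility term;
#'   \item post progression: salvage chemotherapy for the salvage-uptake
#'     fraction during the first `salvage_max_cycles` cycles after
#'     progression, supportive care otherwise, utility `utility_pps`;
#'   \item follow-up cost while alive; one-off terminal-care cost on death;
#'     one-off up-front EGFR test cost divided by the mutation prevalence
#'     for gene-guided strategies.
#' }
#' Costs and QALYs are discounted at `cfg$discount_annual` per year; life
#' years are reported undiscounted.
#'
#' @param strategy A `cea_strategy` (see [build_strategies()]).
#' @param pars Named parameter vector.
#' @param cfg A `cea_config`.
#' @return List with `trace` (data.frame, one row per cycle: occupancies,
#'   undiscounted and discounted cost and QALY increments) and `result`
#'   (one-row data.frame: `strategy`, `cost`, `pf_lys`, `lys`, `qalys`).
#' @export
run_cohort <- function(strategy, pars, cfg = model_config()) {
  stopifnot(inherits(strategy, "cea_strategy"))
  T <- cfg$n_cycles
  A <- cfg$salvage_max_cycles
  pd <- pars[["prob_pps_death"]]
  if (pd < 0 || pd > 1) stop("prob_pps_death outside [0, 1]")
  w <- apply_hazard_ratio(
    weibull_pfs(pars[["weibull_scale"]], pars[["weibull_shape"]]),
    strategy$hr)
  # PFS survival at the start of cycle t is S[t]; the clock advances one
  # cycle index ("cycle" convention) or 21/30.4375 months per cycle
  step <- if (cfg$time_unit == "cycle") 1 else cfg$cycle_days / 30.4375
  S <- survival_at(w, (0:T) * step)
  tp <- 1 - S[-1] / S[-(T + 1)]
  if (any(tp < 0 | tp > 1)) stop("transition probability outside [0, 1] (check hr_", strategy$name, ")")

  # start-of-cycle occupancies for cycles 1..T+1
  pfs <- S[1:(T + 1)]
  pp_age <- matrix(0, T + 1, max(A, 1))     # time-since-progression buckets
  pp_rest <- numeric(T + 1)
  dead <- numeric(T + 1)
  for (t in 1:T) {
    new_prog <- pfs[t] - pfs[t + 1]
    pp_tot <- sum(pp_age[t, ]) + pp_rest[t]
    dead[t + 1] <- dead[t] + pp_tot * pd
    if (A >= 1) {
      surv <- pp_age[t, ] * (1 - pd)
      pp_rest[t + 1] <- (pp_rest[t] * (1 - pd)) + surv[A]
      if (A > 1) pp_age[t + 1, 2:A] <- surv[1:(A - 1)]
      pp_age[t + 1, 1] <- new_prog
    } else {
      pp_rest[t + 1] <- pp_rest[t] * (1 - pd) + new_prog
    }
  }
  occ_sum <- pfs + rowSums(pp_age) + pp_rest + dead
  if (max(abs(occ_sum - 1)) > 1e-9) stop("state occupancy does not sum to 1")

  # accrual occupancies for cycles 1..T
  acc <- function(x) if (cfg$half_cycle) (x[1:T] + x[2:(T + 1)]) / 2 else x[1:T]
  pfs_occ <- acc(pfs)
  salv_occ <- acc(rowSums(pp_age))
  pp_occ <- acc(rowSums(pp_age) + pp_rest)
  alive_occ <- pfs_occ + pp_occ
  new_deaths <- dead[2:(T + 1)] - dead[1:T]
  disc <- discount_factor(cfg, 0:(T - 1))
  cycle_years <- cfg$cycle_days / 365

  # drug schedule per cycle (unit cost while progression free)
  drug_unit <- numeric(T)
  ic <- strategy$induction_cycles
  if (ic > 0) drug_unit[seq_len(min(ic, T))] <- strategy$induction_cost
  if (strategy$continuation_cost > 0) {
    cont <- apply_pap_cap(strategy$continuation_cost, strategy$pap_cap, T)
    idx <- if (ic > 0) (ic + 1):T else 1:T
    # continuation clock starts when continuation starts (TKIs: cycle 1)
    drug_unit[idx] <- cont[seq_along(idx)]
  }
  drug_occ <- if (cfg$induction_billing == "committed" && ic > 0) {
    o <- pfs_occ
    o[seq_len(min(ic, T))] <- alive_occ[seq_len(min(ic, T))]
    o
  } else pfs_occ
  cost_drug <- drug_unit * drug_occ

  on_trt <- if (strategy$on_treatment == "induction") {
    seq_len(T) <= ic
  } else rep(TRUE, T)
  sae_unit <- sae_cost_per_cycle(pars, strategy$sae_prob)
  cost_sae <- ifelse(on_trt, sae_unit, 0) * pfs_occ

  fu_scale <- if (cfg$followup_unit == "month") cfg$cycle_days / 30.4375 else 1
  cost_followup <- pars[["cost_followup_unit"]] * fu_scale * alive_occ
  uptake <- pars[["salvage_uptake"]]
  cost_salvage <- pars[["cost_salvage_cycle"]] * uptake * salv_occ
  cost_supportive <- pars[["cost_supportive_cycle"]] * (pp_occ - uptake * salv_occ)
  cost_terminal <- pars[["cost_terminal_care"]] * new_deaths
  cost_test <- numeric(T)
  if (strategy$egfr_test) {
    cost_test[1] <- pars[["cost_egfr_test"]] / pars[["egfr_prevalence"]]
  }
  cost_total <- cost_drug + cost_sae + cost_followup + cost_salvage +
    cost_supportive + cost_terminal + cost_test

  disutil <- if (cfg$sae_disutility == "on_treatment") {
    ifelse(on_trt, pars[["disutility_sae"]] * strategy$sae_prob, 0) * pfs_occ
  } else numeric(T)
  qaly <- (pfs_occ * pars[["utility_pfs"]] + pp_occ * pars[["utility_pps"]] -
             disutil) * cycle_years
  ly <- alive_occ * cycle_years
  pf_ly <- pfs_occ * cycle_years

  trace <- data.frame(
    cycle = 1:T,
    pfs = pfs[1:T], post_progression = (rowSums(pp_age) + pp_rest)[1:T],
    dead = dead[1:T], new_deaths = new_deaths,
    cost_drug = cost_drug, cost_sae = cost_sae,
    cost_followup = cost_followup, cost_salvage = cost_salvage,
    cost_supportive = cost_supportive, cost_terminal = cost_terminal,
    cost_test = cost_test,
    cost = cost_total, cost_disc = cost_total * disc,
    qaly = qaly, qaly_disc = qaly * disc,
    ly = ly, pf_ly = pf_ly
  )
  result <- data.frame(
    strategy = strategy$name,
    cost = sum(trace$cost_disc),
    pf_lys = sum(pf_ly),
    lys = sum(ly),
    qalys = sum(trace$qaly_disc),
    stringsAsFactors = FALSE
  )
  list(trace = trace, result = result)
}

#' Run the cohort model for a set of strategies
#'
#' @param strategies Named list of `cea_strategy` objects.
#' @param pars Named parameter vector.
#' @param cfg A `cea_config`.
#' @return data.frame with one row per strategy (`strategy`, `cost`,
#'   `pf_lys`, `lys`, `qalys`).
#' @export
run_strategy_set <- function(strategies, pars, cfg = model_config()) {
  do.call(rbind, lapply(strategies, function(s) run_cohort(s, pars, cfg)$result))
}

#' Export a cohort trace to CSV
#'
#' @param trace Trace data.frame from [run_cohort()].
#' @param path Output CSV path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
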
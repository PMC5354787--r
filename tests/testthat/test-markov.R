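cfg <- model_config()
strategies <- build_strategies(the_pars, cfg)

test_that("configuration and discounting follow the model conventions", {
  expect_equal(cfg$n_cycles, 173L)  # floor(365 * 10 / 21)
  expect_equal(discount_factor(cfg, 0), 1.0)
  expect_equal(discount_factor(cfg, 173), 1.05^(-173 * 21 / 365))
  expect_equal(discount_factor(cfg, 173), 0.6155, tolerance = 5e-4)
  expect_true(all(diff(discount_factor(cfg, 0:173)) < 0))
  expect_error(discount_factor(cfg, -1), "non-negative")
})

test_that("strategy construction prices drugs from the published unit costs", {
  # pemetrexed 500 mg/m2 at BSA 1.72 = 860 mg -> two 500 mg vials
  expect_equal(strategies$pc$induction_cost, 2 * 967.57 + 518.4)
  expect_equal(strategies$pemetrexed_maintenance$continuation_cost, 2 * 967.57)
  expect_equal(strategies$gefitinib$continuation_cost, 37.43 * 21)
  expect_equal(strategies$gefitinib$continuation_cost, 786.03)
  expect_equal(strategies$icotinib$continuation_cost, 31.72 * 21)
  expect_equal(strategies$icotinib$continuation_cost, 666.12)
  # exact-milligram billing option
  cfg_mg <- model_config(vial_billing = FALSE)
  s_mg <- build_strategies(the_pars, cfg_mg)
  expect_equal(s_mg$pc$induction_cost, 1.72 * 967.57 + 518.4)
  expect_error(build_strategies(the_pars[1:3], cfg), "missing entries")
})

test_that("SAE costs scale the control cost by cumulative probability ratios", {
  expect_equal(sae_cost_per_cycle(the_pars, the_pars[["prob_sae_control"]]), 507.4)
  expect_equal(sae_cost_per_cycle(the_pars, 0.07), 507.4 * 0.07 / 0.456)
  expect_equal(sae_cost_per_cycle(the_pars, 0.07), 77.89, tolerance = 1e-4)
  expect_equal(sae_cost_per_cycle(the_pars, 0.637), 708.80, tolerance = 1e-4)
  p0 <- the_pars; p0[["prob_sae_control"]] <- 0
  expect_error(sae_cost_per_cycle(p0, 0.07), "positive")
})

test_that("cohort traces conserve occupancy with monotone death and consistent LYs", {
  for (s in strategies) {
    out <- run_cohort(s, the_pars, cfg)
    tr <- out$trace
    occ <- tr$pfs + tr$post_progression + tr$dead
    expect_true(all(abs(occ - 1) < 1e-12), label = s$name)
    expect_true(all(diff(tr$dead) >= -1e-15), label = s$name)
    expect_true(all(diff(tr$pfs) <= 1e-15), label = s$name)
    expect_true(all(tr$new_deaths >= 0))
    # overall LYs = progression-free LYs + post-progression LYs
    pp_ly <- sum(tr$ly) - sum(tr$pf_ly)
    expect_equal(out$result$lys, out$result$pf_lys + pp_ly, tolerance = 1e-9)
    expect_lte(out$result$qalys, out$result$lys)
    expect_lte(out$result$pf_lys, out$result$lys)
  }
})

test_that("zero prices and utilities zero the accruals without touching survival", {
  p0 <- the_pars
  p0[grep("^cost_", names(p0))] <- 0
  p0[c("utility_pfs", "utility_pps", "disutility_sae")] <- 0
  out0 <- run_cohort(build_strategies(p0, cfg)$pc, p0, cfg)
  out1 <- run_cohort(strategies$pc, the_pars, cfg)
  expect_equal(out0$result$cost, 0)
  expect_equal(out0$result$qalys, 0)
  expect_equal(out0$result$lys, out1$result$lys)
})

test_that("an HR of 1 reproduces control survival; lower HRs add QALYs", {
  p1 <- the_pars
  p1[["hr_icotinib"]] <- 1
  s1 <- build_strategies(p1, cfg)
  out_tki <- run_cohort(s1$icotinib, p1, cfg)
  out_pc <- run_cohort(s1$pc, p1, cfg)
  expect_equal(out_tki$result$lys, out_pc$result$lys, tolerance = 1e-12)
  expect_equal(out_tki$result$pf_lys, out_pc$result$pf_lys, tolerance = 1e-12)
  # costs differ only through drug/SAE/test terms
  tr_d <- out_tki$trace; tr_c <- out_pc$trace
  expect_equal(tr_d$cost_followup, tr_c$cost_followup)
  expect_equal(tr_d$cost_salvage, tr_c$cost_salvage)
  expect_equal(tr_d$cost_terminal, tr_c$cost_terminal)
  qalys <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(hr) {
    p <- the_pars; p[["hr_icotinib"]] <- hr
    run_cohort(build_strategies(p, cfg)$icotinib, p, cfg)$result$qalys
  }, numeric(1))
  expect_true(all(diff(qalys) < 0))  # lower HR => more QALYs
})

test_that("five-cycle accruals match a hand-unrolled ledger to 1e-9", {
  cfg5 <- model_config(horizon_years = 0.3)   # floor(365*0.3/21) = 5 cycles
  expect_equal(cfg5$n_cycles, 5L)
  out <- run_cohort(build_strategies(the_pars, cfg5)$pc, the_pars, cfg5)
  oracle <- unroll_control(the_pars, 5)
  expect_equal(out$result$cost, oracle$cost, tolerance = 1e-9)
  expect_equal(out$result$qalys, oracle$qalys, tolerance = 1e-9)
})

test_that("discounting only shrinks accrued QALYs", {
  cfg0 <- model_config(discount_annual = 0)
  q0 <- run_cohort(build_strategies(the_pars, cfg0)$pc, the_pars, cfg0)$result$qalys
  q5 <- run_cohort(strategies$pc, the_pars, cfg)$result$qalys
  expect_gt(q0, q5)
})

test_that("PAP caps truncate cumulative TKI drug cost per the published caps", {
  sched <- apply_pap_cap(666.12, 11077, 30)
  expect_equal(sched[1:16], rep(666.12, 16))       # floor(11077/666.12) = 16
  expect_equal(sched[17], 11077 - 16 * 666.12)
  expect_equal(sched[18:30], rep(0, 13))
  expect_equal(sum(sched), 11077)
  expect_equal(apply_pap_cap(666.12, Inf, 10), rep(666.12, 10))
  expect_error(apply_pap_cap(666.12, -5, 10), "positive")
  # PAP run never costs more than the uncapped run
  pap <- build_strategies(the_pars, cfg, pap = TRUE)
  for (nm in c("gefitinib", "icotinib")) {
    expect_lte(run_cohort(pap[[nm]], the_pars, cfg)$result$cost,
               run_cohort(strategies[[nm]], the_pars, cfg)$result$cost)
    expect_equal(run_cohort(pap[[nm]], the_pars, cfg)$result$qalys,
                 run_cohort(strategies[[nm]], the_pars, cfg)$result$qalys)
  }
})

test_that("trace exports round-trip through CSV", {
  out <- run_cohort(strategies$icotinib, the_pars, short_config())
  path <- tempfile(fileext = ".csv")
  write_trace(out$trace, path)
  back <- read.csv(path)
  expect_equal(back$pfs, out$trace$pfs)
  expect_equal(sum(back$cost_disc), out$result$cost)
})
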
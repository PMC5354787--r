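#!/usr/bin/env Rscript
# Convention calibration: the source tables leave several accounting
# conventions unstated (time unit of the Weibull clock, salvage duration,
# follow-up billing frequency, SAE-disutility duration, half-cycle
# correction, induction billing).  This driver scans the full flag grid,
# scores each combination by RMS relative error against the published
# control-strategy row (cost 22,127; PF-LYs 0.206; overall LYs 1.058;
# QALYs 0.513), and reports the frozen choice exposed as
# calibrated_config().  Only the control row is used: alternative
# strategies never enter the calibration.  Writes results/calibration.csv.

suppressPackageStartupMessages(library(nsclcCEA))
dir.create("results", showWarnings = FALSE)

reg <- build_default_registry()
pars <- base_values(reg)
target <- c(cost = 22127, pf_lys = 0.206, lys = 1.058, qalys = 0.513)

grid <- expand.grid(
  time_unit = c("cycle", "month"),
  salvage_max_cycles = c(4L, 6L),
  followup_unit = c("cycle", "month"),
  sae_disutility = c("on_treatment", "none"),
  half_cycle = c(FALSE, TRUE),
  induction_billing = c("occupancy", "committed"),
  stringsAsFactors = FALSE
)

score <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
  g <- grid[i, ]
  cfg <- model_config(time_unit = g$time_unit,
                      salvage_max_cycles = g$salvage_max_cycles,
                      followup_unit = g$followup_unit,
                      sae_disutility = g$sae_disutility,
                      half_cycle = g$half_cycle,
                      induction_billing = g$induction_billing)
  r <- run_cohort(build_strategies(pars, cfg)$pc, pars, cfg)$result
  got <- c(r$cost, r$pf_lys, r$lys, r$qalys)
  err <- got / target - 1
  cbind(g, cost = r$cost, pf_lys = r$pf_lys, lys = r$lys, qalys = r$qalys,
        cost_err = err[1], rms_err = sqrt(mean(err^2)))
}))
score <- score[order(score$rms_err), ]
write.csv(score, "results/calibration.csv", row.names = FALSE)

cat("Top 5 convention sets by RMS relative error on the control row:\n")
print(head(score, 5), digits = 4, row.names = FALSE)

cat("\nThe life-year and QALY errors are invariant to every flag (they are",
    "\nfixed by the Weibull parameters and the cycle structure), so the cost",
    "\ncell decides.  Frozen choice (= calibrated_config()): cycle time unit,",
    "\n4 salvage cycles, per-cycle follow-up, on-treatment SAE disutility,",
    "\nhalf-cycle correction ON, committed induction billing.\n")

best <- score[1, ]
cat(sprintf("\nControl row at the frozen conventions: cost %.0f (%.1f%% vs 22,127), QALYs %.3f\n",
            best$cost, 100 * best$cost_err, best$qalys))
cat("wrote results/calibration.csv\n")
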
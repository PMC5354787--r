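#!/usr/bin/env Rscript
# Base-case analysis: 10-year discounted cost, life years and QALYs of the
# four first-line strategies, plus the two patient-assistance-program (PAP)
# scenario rows, with pairwise ICERs versus PC and dominance labels.
# Writes results/summary.csv.

suppressPackageStartupMessages(library(nsclcCEA))
dir.create("results", showWarnings = FALSE)

reg <- build_default_registry()
pars <- base_values(reg)
cfg <- calibrated_config()

rs <- run_strategy_set(build_strategies(pars, cfg, pap = FALSE), pars, cfg)
rs_pap <- run_strategy_set(build_strategies(pars, cfg, pap = TRUE)[c("gefitinib", "icotinib")],
                           pars, cfg)
rs_pap$strategy <- paste0(rs_pap$strategy, "_pap")
all6 <- rbind(rs, rs_pap)
inc <- incremental_analysis(all6, reference = "pc")
inc4 <- incremental_analysis(rs, reference = "pc")

smry <- cbind(all6, inc[match(all6$strategy, inc$strategy),
                        c("delta_cost", "delta_qalys", "icer")])
smry$dominance <- inc4$dominance[match(smry$strategy, inc4$strategy)]
smry$dominance[is.na(smry$dominance)] <- "pap_scenario"
rownames(smry) <- NULL
write.csv(smry, "results/summary.csv", row.names = FALSE)

cat("Base-case summary (costs in 2015 US$, discounted at 5%/yr):\n")
print(smry, digits = 4, row.names = FALSE)

cat("\nFindings: icotinib yields the most QALYs of the four strategies and,",
    "\nunder the stated drug prices, is cost-saving versus PC (its first-line",
    "\ndrug bill over the longer progression-free period stays below the",
    "\nfour-cycle pemetrexed-cisplatin induction bill); pemetrexed maintenance",
    "\nand gefitinib are simply dominated by icotinib.  The PAP caps lower",
    "\nboth TKI strategies' costs further.  The published analysis reports",
    "\npositive incremental costs and ICERs of 104,657 / 28,485 / 19,809 $/QALY",
    "\ninstead; its printed table cannot be derived from its own stated",
    "\ninputs (see the methods vignette), so the signed ICERs differ while",
    "\nthe dominance structure agrees.\n")
cat("wrote results/summary.csv\n")
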
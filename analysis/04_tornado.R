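#!/usr/bin/env Rscript
# One-way sensitivity analysis: each varied parameter is set to its lower
# and upper bound in turn and the icotinib-vs-PC ICER recomputed; entries
# are ranked by ICER spread (tornado ordering).  Writes results/tornado.csv.

suppressPackageStartupMessages(library(nsclcCEA))
dir.create("results", showWarnings = FALSE)

reg <- build_default_registry()
cfg <- calibrated_config()

tor <- tornado(reg, cfg, strategy = "icotinib", comparator = "pc")
write.csv(tor, "results/tornado.csv", row.names = FALSE)

cat("Tornado (icotinib vs PC), ranked by ICER spread:\n")
print(tor, digits = 4, row.names = FALSE)

cat("\nThe widest bars are the icotinib hazard ratio, the pemetrexed price",
    "\nand the icotinib daily price: in this engine effectiveness scales",
    "\ndirectly with the hazard ratio (HR^(-1/shape) multiplies mean PFS),",
    "\nso the HR is genuinely influential.  The published ranking (pemetrexed",
    "\ncost, EGFR prevalence, PFS utility on top, HR moderate) implies a far",
    "\nweaker coupling between the HR and accrued QALYs than the stated",
    "\nWeibull machinery produces.\n")
cat("wrote results/tornado.csv\n")
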
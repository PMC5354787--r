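cfg <- calibrated_config()

test_that("incremental analysis computes pairwise ICERs and dominance labels", {
  res <- data.frame(
    strategy = c("pc", "a", "b", "c"),
    cost = c(22127, 22127 + 1862, 22127 + 9519, 22127 + 500),
    qalys = c(0.513, 0.513 + 0.094, 0.513 + 0.091, 0.500)
  )
  inc <- incremental_analysis(res, reference = "pc")
  expect_equal(inc$delta_cost[inc$strategy == "a"], 1862)
  expect_equal(inc$icer[inc$strategy == "a"], 1862 / 0.094)
  expect_equal(inc$icer[inc$strategy == "a"], 19809, tolerance = 5e-5)
  expect_equal(inc$icer[inc$strategy == "b"], 9519 / 0.091)
  expect_true(is.na(inc$icer[inc$strategy == "pc"]))
  expect_equal(inc$dominance[inc$strategy == "pc"], "reference")
  # c costs more and yields fewer QALYs than pc -> simply dominated
  expect_equal(inc$dominance[inc$strategy == "c"], "simple_dominated")
  # b costs more per QALY than a for fewer QALYs -> dominated too
  expect_equal(inc$dominance[inc$strategy == "b"], "simple_dominated")
  expect_equal(inc$dominance[inc$strategy == "a"], "on_frontier")
  expect_error(incremental_analysis(rbind(res, res[2, ])), "duplicate")
  expect_error(incremental_analysis(res, reference = "zzz"), "missing")
})

test_that("a strategy identical to the reference ties at zero increments", {
  res <- data.frame(strategy = c("pc", "twin"), cost = c(100, 100),
                    qalys = c(0.5, 0.5))
  inc <- incremental_analysis(res, reference = "pc")
  expect_equal(inc$delta_cost[2], 0)
  expect_equal(inc$delta_qalys[2], 0)
  expect_true(is.na(inc$icer[2]))
})

test_that("extended dominance removes frontier points with non-increasing ICERs", {
  res <- data.frame(
    strategy = c("ref", "mid", "top"),
    cost = c(0, 900, 1000),
    qalys = c(0, 0.1, 1.0)
  )
  inc <- incremental_analysis(res, reference = "ref")
  # mid: 9000/QALY to reach, but skipping to top costs 1000/QALY overall
  expect_equal(inc$dominance[inc$strategy == "mid"], "extended_dominated")
  expect_equal(inc$dominance[inc$strategy == "top"], "on_frontier")
})

test_that("ICERs are invariant to a constant one-off cost on every strategy", {
  pars <- the_pars
  rs <- run_strategy_set(build_strategies(pars, cfg), pars, cfg)
  inc <- incremental_analysis(rs)
  rs2 <- rs
  rs2$cost <- rs2$cost + 5000
  inc2 <- incremental_analysis(rs2)
  expect_equal(inc2$delta_cost, inc$delta_cost)
  expect_equal(inc2$icer, inc$icer)
})

test_that("tornado orders parameters by ICER spread and keeps degenerate entries last", {
  tor <- tornado(the_registry, cfg)
  expect_true(all(diff(tor$spread) <= 0))
  expect_true(all(tor$spread >= 0))
  # degenerate range collapses the spread to zero and ranks last
  reg0 <- the_registry
  reg0$utility_pps$low <- reg0$utility_pps$high <- reg0$utility_pps$base
  tor0 <- tornado(reg0, cfg, parameters = c("utility_pps", "cost_pemetrexed_500mg"))
  expect_equal(tor0$parameter[nrow(tor0)], "utility_pps")
  expect_equal(tor0$spread[nrow(tor0)], 0)
  # raising the comparator drug (pemetrexed) price moves the icotinib-vs-PC
  # ICER monotonically down (control gets dearer)
  row <- tor[tor$parameter == "cost_pemetrexed_500mg", ]
  expect_lt(row$icer_at_high, row$icer_at_low)
})

test_that("PSA is seed-reproducible and degenerate distributions reproduce the base case", {
  reg <- the_registry
  a <- run_psa(reg, cfg, n = 10, seed = 5)
  b <- run_psa(reg, cfg, n = 10, seed = 5)
  expect_identical(a, b)
  dreg <- degenerate_registry(reg)
  d <- run_psa(dreg, cfg, n = 5, seed = 9)
  base <- run_strategy_set(build_strategies(the_pars, cfg), the_pars, cfg)
  for (i in 1:5) {
    di <- d[d$draw == i, ]
    expect_equal(di$cost, base$cost, tolerance = 1e-12)
    expect_equal(di$qalys, base$qalys, tolerance = 1e-12)
  }
  # mean PSA control cost stays near the base-case cost
  psa <- run_psa(reg, cfg, n = 200, seed = 11)
  mc <- mean(psa$cost[psa$strategy == "pc"])
  expect_lt(abs(mc - base$cost[base$strategy == "pc"]) / base$cost[base$strategy == "pc"], 0.1)
})

test_that("CEAC probabilities are proper and reduce to cost minimization at lambda 0", {
  psa <- run_psa(the_registry, cfg, n = 50, seed = 3)
  cc <- ceac(psa, thresholds = seq(0, 60000, by = 10000))
  sums <- as.numeric(tapply(cc$prob_cost_effective, cc$threshold, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-12)
  expect_true(all(cc$prob_cost_effective >= 0 & cc$prob_cost_effective <= 1))
  # at lambda = 0 the cheapest strategy wins every draw
  cc0 <- ceac(psa, thresholds = 0)
  cheapest <- vapply(split(psa, psa$draw),
                     function(d) d$strategy[which.min(d$cost)], character(1))
  tab <- table(factor(cheapest, levels = unique(psa$strategy))) / length(cheapest)
  expect_equal(cc0$prob_cost_effective, as.numeric(tab[cc0$strategy]))
  # single strategy: probability 1 everywhere
  solo <- psa[psa$strategy == "pc", ]
  cc1 <- ceac(solo, thresholds = c(0, 22200))
  expect_equal(cc1$prob_cost_effective, c(1, 1))
  expect_error(ceac(psa[0, ]), "empty")
  expect_error(ceac(psa, thresholds = numeric(0)), "empty")
})

test_that("CEAC splits exact net-monetary-benefit ties equally", {
  psa <- data.frame(draw = c(1, 1), strategy = c("a", "b"),
                    cost = c(10, 10), qalys = c(0.5, 0.5))
  cc <- ceac(psa, thresholds = 1000)
  expect_equal(cc$prob_cost_effective, c(0.5, 0.5))
})
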
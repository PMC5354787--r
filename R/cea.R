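#' Incremental cost-effectiveness analysis
#'
#' Compares every strategy pairwise against the reference (incremental cost,
#' incremental QALYs, ICER) and classifies dominance on the
#' cost-effectiveness frontier:
#' \itemize{
#'   \item `simple_dominated`: some other strategy yields at least as many
#'     QALYs for at most the cost (strictly better on one axis);
#'   \item `extended_dominated`: removed when building the efficient
#'     frontier because a convex combination of neighbours dominates it;
#'   \item `on_frontier` otherwise; the reference row is labelled
#'     `reference`.
#' }
#'
#' @param results data.frame with columns `strategy`, `cost`, `qalys` (one
#'   row per strategy, e.g. from [run_strategy_set()]).
#' @param reference Reference strategy name.
#' @return data.frame with columns `strategy`, `comparator`, `delta_cost`,
#'   `delta_qalys`, `icer` (NA for the reference and for zero-QALY
#'   differences), `dominance`.
#' @export
incremental_analysis <- function(results, reference = "pc") {
  if (anyDuplicated(results$strategy)) stop("duplicate strategy names")
  if (!reference %in% results$strategy) stop("reference strategy '", reference, "' missing")
  ref <- results[results$strategy == reference, ]
  dc <- results$cost - ref$cost
  dq <- results$qalys - ref$qalys
  icer <- ifelse(dq != 0, dc / dq, NA_real_)
  icer[results$strategy == reference] <- NA_real_

  # simple dominance: another strategy weakly better on both axes, strictly
  # better on at least one
  n <- nrow(results)
  simple <- vapply(seq_len(n), function(i) {
    any(results$cost <= results$cost[i] & results$qalys >= results$qalys[i] &
          (results$cost < results$cost[i] | results$qalys > results$qalys[i]))
  }, logical(1))
  # extended dominance on the remaining candidates: walk the frontier in
  # increasing QALY order and drop points with non-increasing incremental
  # ICERs
  label <- ifelse(simple, "simple_dominated", "on_frontier")
  cand <- which(!simple)
  cand <- cand[order(results$qalys[cand], results$cost[cand])]
  repeat {
    if (length(cand) < 3) break
    dropped <- FALSE
    for (j in 2:(length(cand) - 1)) {
      lo <- cand[j - 1]; mid <- cand[j]; hi <- cand[j + 1]
      icer_in <- (results$cost[mid] - results$cost[lo]) /
        (results$qalys[mid] - results$qalys[lo])
      icer_out <- (results$cost[hi] - results$cost[mid]) /
        (results$qalys[hi] - results$qalys[mid])
      if (icer_in >= icer_out) {
        label[mid] <- "extended_dominated"
        cand <- cand[-j]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  label[results$strategy == reference] <- "reference"
  data.frame(strategy = results$strategy, comparator = reference,
             delta_cost = dc, delta_qalys = dq, icer = icer,
             dominance = label, stringsAsFactors = FALSE)
}

# base-case ICER of strategy vs comparator under a given parameter vector
pair_icer <- function(pars, cfg, strategy, comparator, pap = FALSE) {
  strategies <- build_strategies(pars, cfg, pap = pap)
  rs <- run_strategy_set(strategies[c(comparator, strategy)], pars, cfg)
  dq <- rs$qalys[2] - rs$qalys[1]
  if (dq == 0) return(NA_real_)
  (rs$cost[2] - rs$cost[1]) / dq
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the base-case pairwise comparison twice per varied parameter,
#' holding everything else at base, with the parameter set to its lower and
#' upper bound; entries are ordered by decreasing ICER spread.
#'
#' @param reg A `cea_registry`.
#' @param cfg A `cea_config`.
#' @param strategy,comparator Strategy pair whose ICER is examined
#'   (defaults: icotinib vs PC).
#' @param pap Logical; apply the patient-assistance-program caps.
#' @param parameters Names of registry entries to vary; default: every
#'   entry flagged `vary` in the registry.
#' @return data.frame with columns `parameter`, `low`, `high`,
#'   `icer_at_low`, `icer_at_high`, `spread`, sorted by `spread`
#'   (decreasing); non-finite ICERs at a bound are kept and flagged in
#'   `note`.
#' @export
tornado <- function(reg, cfg = model_config(), strategy = "icotinib",
                    comparator = "pc", pap = FALSE, parameters = NULL) {
  stopifnot(inherits(reg, "cea_registry"))
  if (is.null(parameters)) {
    parameters <- names(reg)[vapply(reg, function(e) isTRUE(e$vary), logical(1))]
  }
  base <- base_values(reg)
  rows <- lapply(parameters, function(nm) {
    e <- reg[[nm]]
    icers <- vapply(c(e$low, e$high), function(v) {
      p <- base
      p[nm] <- v
      pair_icer(p, cfg, strategy, comparator, pap = pap)
    }, numeric(1))
    data.frame(parameter = nm, low = e$low, high = e$high,
               icer_at_low = icers[1], icer_at_high = icers[2],
               spread = abs(icers[2] - icers[1]),
               note = if (all(is.finite(icers))) "" else "non-finite ICER at bound",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` Monte Carlo parameter sets from the registry distributions and
#' evaluates every strategy on each common draw.
#'
#' @param reg A `cea_registry`.
#' @param cfg A `cea_config`.
#' @param n Number of draws (default 1000).
#' @param seed Integer seed; the run is reproducible given the seed.
#' @param pap Logical; apply the patient-assistance-program caps.
#' @return data.frame in long format: `draw`, `strategy`, `cost`, `qalys`.
#' @export
run_psa <- function(reg, cfg = model_config(), n = 1000, seed = 1, pap = FALSE) {
  stopifnot(inherits(reg, "cea_registry"), n >= 1)
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pars <- sample_parameters(reg)
    rs <- run_strategy_set(build_strategies(pars, cfg, pap = pap), pars, cfg)
    out[[i]] <- data.frame(draw = i, strategy = rs$strategy,
                           cost = rs$cost, qalys = rs$qalys,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay threshold, a strategy's acceptability is the
#' fraction of PSA draws in which its net monetary benefit
#' (`threshold * QALYs - cost`) is maximal; ties are split equally.
#'
#' @param psa PSA output from [run_psa()].
#' @param thresholds Threshold grid, $/QALY (default 0 to 60,000 by 500).
#' @return data.frame in long format: `threshold`, `strategy`,
#'   `prob_cost_effective`; probabilities sum to 1 at each threshold.
#' @export
ceac <- function(psa, thresholds = seq(0, 60000, by = 500)) {
  if (!nrow(psa)) stop("PSA output is empty")
  if (!length(thresholds)) stop("threshold grid is empty")
  strategies <- unique(psa$strategy)
  draws <- split(psa, psa$draw)
  qmat <- vapply(draws, function(d) d$qalys[match(strategies, d$strategy)],
                 numeric(length(strategies)))
  cmat <- vapply(draws, function(d) d$cost[match(strategies, d$strategy)],
                 numeric(length(strategies)))
  qmat <- matrix(qmat, nrow = length(strategies))
  cmat <- matrix(cmat, nrow = length(strategies))
  rows <- lapply(thresholds, function(lambda) {
    nmb <- lambda * qmat - cmat
    wins <- apply(nmb, 2, function(col) {
      best <- max(col)
      hit <- abs(col - best) < 1e-9
      hit / sum(hit)       # split ties equally
    })
    wins <- matrix(wins, nrow = length(strategies))
    data.frame(threshold = lambda, strategy = strategies,
               prob_cost_effective = rowMeans(wins),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
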
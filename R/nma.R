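#' Trial-level effects and the evidence network
#'
#' `read_trial_effects()` loads a trial table (columns `study`, `treat_a`,
#' `treat_b`, `hr`, `ci_low`, `ci_high`; each row the hazard ratio of
#' `treat_a` versus `treat_b` with its 95% CI).  The packaged table holds the
#' six first-line PFS comparisons connecting PC, pemetrexed maintenance,
#' non-pemetrexed platinum chemotherapy, gefitinib and icotinib.
#'
#' @param path CSV path; defaults to the packaged trial table.
#' @return data.frame of trial effects.
#' @export
read_trial_effects <- function(path = system.file("extdata", "pfs_trials.csv",
                                                  package = "nsclcCEA")) {
  eff <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study", "treat_a", "treat_b", "hr", "ci_low", "ci_high")
  if (!all(need %in% names(eff))) {
    stop("trial table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- !(eff$ci_low > 0 & eff$ci_low <= eff$hr & eff$hr <= eff$ci_high)
  if (any(bad)) {
    stop("invalid CI ordering for studies: ", paste(eff$study[bad], collapse = ", "))
  }
  eff
}

#' Log hazard ratio and standard error from a 95% confidence interval
#'
#' `logHR = ln(hr)`; `SE = (ln(ci_high) - ln(ci_low)) / 3.92` (the CI spans
#' 2 x 1.96 standard errors on the log scale).
#'
#' @param hr Hazard ratio point estimate(s).
#' @param ci_low,ci_high 95% CI bounds.
#' @return data.frame with columns `loghr` and `se`.
#' @export
#' @examples
#' loghr_from_ci(0.48, 0.36, 0.64)
loghr_from_ci <- function(hr, ci_low, ci_high) {
  if (any(hr <= 0 | ci_low <= 0 | ci_high <= 0)) {
    stop("hazard ratios and CI bounds must be positive")
  }
  data.frame(loghr = log(hr), se = (log(ci_high) - log(ci_low)) / 3.92)
}

#' DerSimonian-Laird random-effects pooling of one comparison
#'
#' Moment-based random-effects meta-analysis on the log hazard-ratio scale:
#' fixed-effect weights `w = 1/SE^2`, Cochran's
#' `Q = sum(w * (y - yhat)^2)`, `tau2 = max(0, (Q - df) / (sum(w) -
#' sum(w^2)/sum(w)))`, random-effects weights `1/(SE^2 + tau2)`.
#'
#' @param loghr Study log hazard ratios (same comparison).
#' @param se Study standard errors.
#' @return List with `loghr` (pooled), `se`, `Q`, `df`, `tau2`, `i2`
#'   (percent, `max(0, (Q - df)/Q) * 100`).
#' @export
pool_random_effects <- function(loghr, se) {
  k <- length(loghr)
  if (k == 0) stop("no effects to pool")
  stopifnot(length(se) == k, all(se > 0))
  w <- 1 / se^2
  yfix <- sum(w * loghr) / sum(w)
  Q <- sum(w * (loghr - yfix)^2)
  df <- k - 1
  tau2 <- if (df > 0) max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w))) else 0
  wre <- 1 / (se^2 + tau2)
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(loghr = sum(wre * loghr) / sum(wre),
       se = sqrt(1 / sum(wre)),
       Q = Q, df = df, tau2 = tau2, i2 = i2)
}

#' Frequentist random-effects network meta-analysis of hazard ratios
#'
#' Estimates each treatment's log hazard ratio versus the reference by
#' inverse-variance weighted least squares on the network design matrix
#' (row per study: +1 for `treat_a`, -1 for `treat_b`, reference column
#' dropped).  Heterogeneity uses a single network-wide `tau2` from the
#' generalized DerSimonian-Laird moment estimator with
#' `df = n_studies - (n_nodes - 1)`; random-effects weights
#' `1/(SE^2 + tau2)` then re-fit the treatment effects.  For a loop-free
#' network the node estimates equal products of the pooled edge hazard
#' ratios.
#'
#' @param effects Trial-effects data.frame (see [read_trial_effects()]).
#' @param reference Reference treatment label (default `"pc"`).
#' @return List of class `nma_result`: `pooled` (data.frame with
#'   `treatment`, `loghr`, `se`, `hr`, `ci_low`, `ci_high`; reference row
#'   has loghr 0, se 0), `tau2`, `Q`, `df`, `i2`, `reference`.
#' @export
#' @examples
#' nma <- nma_estimate(read_trial_effects())
#' nma$pooled
nma_estimate <- function(effects, reference = "pc") {
  nodes <- sort(unique(c(effects$treat_a, effects$treat_b)))
  if (!reference %in% nodes) stop("reference '", reference, "' not in network")
  # connectivity check
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(effects))) {
      a <- effects$treat_a[i]; b <- effects$treat_b[i]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp %in% c(comp[a], comp[b])] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(unique(comp)) > 1) {
    groups <- split(names(comp), comp)
    stop("evidence network is disconnected; components: ",
         paste(vapply(groups, paste, character(1), collapse = "+"), collapse = " | "))
  }
  est <- loghr_from_ci(effects$hr, effects$ci_low, effects$ci_high)
  y <- est$loghr
  se <- est$se
  others <- setdiff(nodes, reference)
  X <- matrix(0, nrow(effects), length(others), dimnames = list(effects$study, others))
  for (i in seq_len(nrow(effects))) {
    if (effects$treat_a[i] != reference) X[i, effects$treat_a[i]] <- 1
    if (effects$treat_b[i] != reference) X[i, effects$treat_b[i]] <- -1
  }
  wls <- function(W) {
    XtW <- t(X * W)
    A <- XtW %*% X
    beta <- solve(A, XtW %*% y)
    list(beta = drop(beta), cov = solve(A))
  }
  w_fix <- 1 / se^2
  fit_fix <- wls(w_fix)
  resid <- y - drop(X %*% fit_fix$beta)
  Q <- sum(w_fix * resid^2)
  df <- nrow(effects) - length(others)
  if (df < 0) stop("more treatment parameters than studies; network under-identified")
  # generalized DL: C = tr(W) - tr((X'WX)^{-1} X'W^2X)
  A <- t(X * w_fix) %*% X
  C <- sum(w_fix) - sum(diag(solve(A, t(X * w_fix^2) %*% X)))
  tau2 <- if (df > 0) max(0, (Q - df) / C) else 0
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  fit_re <- wls(1 / (se^2 + tau2))
  se_re <- sqrt(diag(fit_re$cov))
  pooled <- data.frame(
    treatment = c(reference, others),
    loghr = c(0, unname(fit_re$beta[others])),
    se = c(0, unname(se_re[others])),
    stringsAsFactors = FALSE
  )
  pooled$hr <- exp(pooled$loghr)
  pooled$ci_low <- exp(pooled$loghr - 1.96 * pooled$se)
  pooled$ci_high <- exp(pooled$loghr + 1.96 * pooled$se)
  structure(list(pooled = pooled, tau2 = tau2, Q = Q, df = df, i2 = i2,
                 reference = reference),
            class = "nma_result")
}

#' @export
print.nma_result <- function(x, ...) {
  cat(sprintf("<nma_result> reference = %s; Q = %.3f on %d df; tau2 = %.4f; I2 = %.1f%%\n",
              x$reference, x$Q, x$df, x$tau2, x$i2))
  print(x$pooled, digits = 4)
  invisible(x)
}

#' Hazard ratio of a treatment versus the network reference
#'
#' @param nma An `nma_result`.
#' @param treatment Treatment label.
#' @return Hazard ratio (numeric).
#' @export
nma_hr <- function(nma, treatment) {
  i <- match(treatment, nma$pooled$treatment)
  if (is.na(i)) stop("treatment '", treatment, "' not in NMA result")
  nma$pooled$hr[i]
}
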
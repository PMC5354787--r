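#' Generate a synthetic Kaplan-Meier PFS curve from known Weibull truth
#'
#' Draws Weibull event times (`S(t) = exp(-scale * t^shape)`) and
#' independent exponential censoring times, then computes the product-limit
#' estimate.  Used to exercise the curve-fitting stage with known truth.
#'
#' @param true_scale,true_shape Weibull parameters of the event-time
#'   distribution.
#' @param n_subjects Number of subjects (>= 10).
#' @param censor_rate Exponential censoring rate per time unit (>= 0; 0
#'   disables censoring).
#' @param seed Integer seed; the curve is a pure function of the arguments.
#' @return data.frame with columns `time`, `survival`, `at_risk` (one row
#'   per distinct event time).
#' @export
#' @examples
#' km <- gen_km_curve(0.1029, 1.3077, n_subjects = 200, seed = 7)
#' fit_weibull(km)$model
gen_km_curve <- function(true_scale, true_shape, n_subjects = 500,
                         censor_rate = 0.02, seed = 1) {
  stopifnot(true_scale > 0, true_shape > 0, n_subjects >= 10, censor_rate >= 0)
  set.seed(seed)
  # rweibull uses S(t) = exp(-(t/b)^a): a = shape, b = scale^(-1/shape)
  event <- stats::rweibull(n_subjects, shape = true_shape,
                           scale = true_scale^(-1 / true_shape))
  cens <- if (censor_rate > 0) stats::rexp(n_subjects, rate = censor_rate) else rep(Inf, n_subjects)
  time <- pmin(event, cens)
  status <- as.integer(event <= cens)
  if (sum(status) == 0) stop("all subjects censored before the first event")
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], survival = fit$surv[keep],
             at_risk = fit$n.risk[keep])
}

#' Generate a synthetic multi-trial hazard-ratio network
#'
#' For each edge of a specified network, simulates trials whose log hazard
#' ratio is the edge's true effect plus a `Normal(0, tau2)` between-study
#' effect plus `Normal(0, SE^2)` sampling error, and reports each trial as
#' a hazard ratio with 95% CI.  Used to test the pooling and network
#' stages against known truth.
#'
#' @param edges data.frame with columns `treat_a`, `treat_b`, `true_loghr`.
#' @param tau2 Between-study variance on the log-HR scale (>= 0).
#' @param trials_per_edge Trials simulated per edge (>= 1).
#' @param se_range Length-2 range from which each trial's standard error is
#'   drawn uniformly.
#' @param seed Integer seed.
#' @return Trial-effects data.frame (`study`, `treat_a`, `treat_b`, `hr`,
#'   `ci_low`, `ci_high`), valid input to [nma_estimate()].
#' @export
gen_nma_trials <- function(edges, tau2 = 0.05, trials_per_edge = 3,
                           se_range = c(0.1, 0.25), seed = 1) {
  stopifnot(tau2 >= 0, trials_per_edge >= 1, length(se_range) == 2,
            all(se_range > 0))
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(edges))) {
    for (j in seq_len(trials_per_edge)) {
      se <- stats::runif(1, se_range[1], se_range[2])
      y <- edges$true_loghr[i] +
        stats::rnorm(1, 0, sqrt(tau2)) + stats::rnorm(1, 0, se)
      rows[[length(rows) + 1]] <- data.frame(
        study = sprintf("%s_vs_%s_trial%d", edges$treat_a[i], edges$treat_b[i], j),
        treat_a = edges$treat_a[i], treat_b = edges$treat_b[i],
        hr = exp(y), ci_low = exp(y - 1.96 * se), ci_high = exp(y + 1.96 * se),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
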
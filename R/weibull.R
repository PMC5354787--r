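#' Weibull progression-free-survival model
#'
#' The PFS curve is modelled as `S(t) = exp(-scale * t^shape)` with time `t`
#' counted in model cycles (21 days) by default.  `shape > 1` corresponds to
#' an increasing hazard of progression.
#'
#' @param scale Weibull scale (lambda), > 0, per `time_unit^shape`.
#' @param shape Weibull shape (gamma), > 0, dimensionless.
#' @param time_unit Time unit of `t`: `"cycle"` (21 days, default) or
#'   `"month"`.
#' @return An object of class `weibull_pfs`.
#' @export
#' @examples
#' w <- weibull_pfs(0.1029, 1.3077)
#' survival_at(w, 1)
weibull_pfs <- function(scale, shape, time_unit = c("cycle", "month")) {
  time_unit <- match.arg(time_unit)
  stopifnot(is.numeric(scale), is.numeric(shape), length(scale) == 1, length(shape) == 1)
  if (scale <= 0 || shape <= 0) stop("Weibull scale and shape must be positive")
  structure(list(scale = scale, shape = shape, time_unit = time_unit),
            class = "weibull_pfs")
}

#' @export
print.weibull_pfs <- function(x, ...) {
  cat(sprintf("<weibull_pfs> scale = %.6g, shape = %.6g (time in %ss)\n",
              x$scale, x$shape, x$time_unit))
  invisible(x)
}

#' Survival probability of a Weibull PFS model
#'
#' @param w A `weibull_pfs`.
#' @param t Time (same unit as the model), vectorized, >= 0.
#' @return `exp(-scale * t^shape)`.
#' @export
survival_at <- function(w, t) {
  stopifnot(inherits(w, "weibull_pfs"))
  if (any(t < 0)) stop("time must be non-negative")
  exp(-w$scale * t^w$shape)
}

#' Per-cycle probability of leaving progression-free survival
#'
#' Probability of progressing during cycle `t` conditional on being
#' progression free at its start:
#' `P(t) = 1 - exp(scale * (t-1)^shape - scale * t^shape)`,
#' so that `prod_{k=1..t} (1 - P(k)) = S(t)` exactly.
#'
#' @param w A `weibull_pfs`.
#' @param t Cycle index (integer-valued, >= 1), vectorized.
#' @return Transition probability in (0, 1).
#' @export
cycle_transition_prob <- function(w, t) {
  stopifnot(inherits(w, "weibull_pfs"))
  if (any(t < 1)) stop("cycle index must be >= 1")
  1 - exp(w$scale * (t - 1)^w$shape - w$scale * t^w$shape)
}

#' Apply a hazard ratio to a Weibull PFS model
#'
#' Under proportional hazards a hazard ratio `hr` multiplies the Weibull
#' scale and leaves the shape unchanged: the adjusted model is
#' `(scale * hr, shape)`.
#'
#' @param w A `weibull_pfs`.
#' @param hr Hazard ratio, > 0.
#' @return The adjusted `weibull_pfs`.
#' @export
apply_hazard_ratio <- function(w, hr) {
  stopifnot(inherits(w, "weibull_pfs"), length(hr) == 1)
  if (!is.finite(hr) || hr <= 0) stop("hazard ratio must be positive")
  weibull_pfs(w$scale * hr, w$shape, w$time_unit)
}

#' Fit a Weibull model to a Kaplan-Meier curve by log-log least squares
#'
#' Linearizes `S(t) = exp(-scale * t^shape)` as
#' `ln(-ln S) = ln(scale) + shape * ln(t)` and fits ordinary least squares,
#' reporting the r-squared on that linearized scale.  Points with `t <= 0`
#' or `S` outside (0, 1) are excluded (the log-log transform is undefined
#' there).
#'
#' @param km A data.frame with columns `time` and `survival` (a `KMCurve`),
#'   survival non-increasing in `[0, 1]`.
#' @param time_unit Time unit of the fitted model.
#' @return List with elements `model` (a `weibull_pfs`) and `r_squared`.
#' @export
#' @examples
#' w <- weibull_pfs(0.1029, 1.3077)
#' km <- data.frame(time = 1:20, survival = survival_at(weibull_pfs(0.1029, 1.3077), 1:20))
#' fit_weibull(km)$model
fit_weibull <- function(km, time_unit = c("cycle", "month")) {
  time_unit <- match.arg(time_unit)
  if (!all(c("time", "survival") %in% names(km))) {
    stop("km must have columns 'time' and 'survival'")
  }
  keep <- km$time > 0 & km$survival > 0 & km$survival < 1
  t <- km$time[keep]
  s <- km$survival[keep]
  if (length(t) < 3) stop("need at least 3 points with 0 < survival < 1 and time > 0")
  y <- log(-log(s))
  x <- log(t)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  # r-squared on the linearized scale (avoids summary.lm's perfect-fit warning)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(model = weibull_pfs(exp(unname(co[1])), unname(co[2]), time_unit),
       r_squared = r2)
}

#' Read / write a Kaplan-Meier curve as CSV
#'
#' Two-column CSV with header `time,survival`.
#'
#' @param path File path.
#' @return `read_km_curve` returns a data.frame with columns `time` and
#'   `survival`.
#' @export
read_km_curve <- function(path) {
  km <- utils::read.csv(path)
  if (!all(c("time", "survival") %in% names(km))) {
    stop("KM curve file must have columns 'time' and 'survival': ", path)
  }
  if (any(diff(km$survival) > 1e-12)) stop("survival column must be non-increasing")
  if (any(km$survival < 0 | km$survival > 1)) stop("survival values must be in [0, 1]")
  km[c("time", "survival")]
}

#' @rdname read_km_curve
#' @param km A KM curve data.frame.
#' @export
write_km_curve <- function(km, path) {
  utils::write.csv(km[c("time", "survival")], path, row.names = FALSE)
  invisible(path)
}
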
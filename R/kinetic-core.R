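#' First-order kinetics with a baseline plateau
#'
#' Shared kinetic model for metabolic-labeling time courses. The fraction of
#' unlabeled signal remaining at time t is modeled as
#' \deqn{y(t) = b + (1 - b) e^{-k t}}
#' where k is the observed clearance rate constant (1/day) and b a constant
#' fractional baseline at infinite time. The observed protein clearance rate
#' decomposes as k_t = k_deg + k_div: proteolytic degradation plus dilution by
#' cell division.
#'
#' @name kinetic-core
NULL

#' Convert a first-order rate constant to a half-life
#'
#' @param k Rate constant in 1/day; must be positive.
#' @return Half-life in days, `log(2)/k`.
#' @examples
#' half_life(log(2) / 3) # 3 days
#' @export
half_life <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("half_life() requires a positive, finite rate constant")
  }
  log(2) / k
}

#' Convert a half-life in days to a first-order rate constant
#'
#' @param t_half Half-life in days; must be positive.
#' @return Rate constant in 1/day.
#' @export
rate_from_half_life <- function(t_half) {
  if (any(!is.finite(t_half)) || any(t_half <= 0)) {
    stop("rate_from_half_life() requires a positive, finite half-life")
  }
  log(2) / t_half
}

#' Fit a first-order decay with baseline to a labeling time course
#'
#' Least-squares fit of `value = baseline + (1 - baseline) * exp(-k * time)`
#' using bounded Levenberg-Marquardt. Initial values come from a log-linear
#' regression of the baseline-subtracted values; the standard error of k is
#' the Jacobian-based (local curvature) estimate at the optimum.
#'
#' Observations from multiple replicates may be pooled: the fit treats every
#' (time, value) pair as one observation and is invariant to observation
#' order and replicate relabeling.
#'
#' @param times Numeric vector of times in days (non-negative).
#' @param values Numeric vector of normalized unlabeled-fraction values.
#' @param k_bounds Length-2 numeric, search bounds for k (1/day).
#' @param baseline_bounds Length-2 numeric, bounds for the baseline fraction.
#' @return A list of class `turnover_fit` with elements `k_t`, `se_k`,
#'   `baseline`, `r2`, `t_stat`, `p_value`, `half_life`, `n_points`,
#'   `converged`. Failed fits are returned with `converged = FALSE` and NA
#'   estimates rather than raising, so batch runs continue.
#' @examples
#' t <- c(0, 2, 4, 8, 16, 32)
#' fit <- fit_first_order_decay(t, 0.1 + 0.9 * exp(-0.5 * t))
#' fit$k_t
#' @export
fit_first_order_decay <- function(times, values,
                                  k_bounds = c(1e-6, 10),
                                  baseline_bounds = c(0, 0.95)) {
  stopifnot(length(times) == length(values))
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop("times and values must be finite")
  }
  if (any(times < 0)) stop("times must be non-negative")
  if (length(unique(times)) < 3) {
    stop("fitting requires at least 3 distinct timepoints")
  }
  if (any(values < -0.1) || any(values > 1.5)) {
    stop("values outside the tolerated range [-0.1, 1.5]")
  }

  n <- length(values)
  start <- .decay_start(times, values, k_bounds, baseline_bounds)
  model <- function(p) p["b"] + (1 - p["b"]) * exp(-p["k"] * times)
  # Jacobian of the residuals (y - model) w.r.t. (k, b)
  jac <- function(p) {
    e <- exp(-p["k"] * times)
    cbind(k = (1 - p["b"]) * times * e, b = -(1 - e))
  }
  fit <- .bounded_lm(
    resid_fn = function(p) values - model(p), jac_fn = jac,
    start = c(k = start$k, b = start$b),
    lower = c(k = k_bounds[1], b = baseline_bounds[1]),
    upper = c(k = k_bounds[2], b = baseline_bounds[2]))
  if (!fit$converged) {
    return(structure(
      list(k_t = NA_real_, se_k = NA_real_, baseline = NA_real_, r2 = NA_real_,
           t_stat = NA_real_, p_value = NA_real_, half_life = NA_real_,
           n_points = n, converged = FALSE),
      class = "turnover_fit"
    ))
  }

  k_hat <- fit$par[["k"]]
  b_hat <- fit$par[["b"]]
  se_k <- fit$se[["k"]]
  ss_res <- fit$deviance
  ss_tot <- sum((values - mean(values))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  gs <- goodness_stats(k_hat, se_k, n_points = n)

  structure(
    list(k_t = k_hat, se_k = se_k, baseline = b_hat, r2 = r2,
         t_stat = gs$t_stat, p_value = gs$p_value,
         half_life = if (k_hat > 0) log(2) / k_hat else NA_real_,
         n_points = n, converged = TRUE),
    class = "turnover_fit"
  )
}

# Bounded Levenberg-Marquardt least squares around minpack.lm::nls.lm, with
# a Jacobian-based covariance computed here: the nls.lm summary method fails
# on exact (zero-residual) fits, where the correct SE is simply 0.
.bounded_lm <- function(resid_fn, jac_fn, start, lower, upper) {
  res <- tryCatch(
    minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper,
      fn = resid_fn, jac = jac_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL
  )
  if (is.null(res) || !res$info %in% 1:4) {
    return(list(converged = FALSE, par = start,
                se = stats::setNames(rep(NA_real_, length(start)),
                                     names(start)),
                deviance = NA_real_))
  }
  par <- stats::setNames(as.numeric(res$par), names(start))
  n <- length(resid_fn(par))
  p <- length(par)
  sigma2 <- if (n > p) res$deviance / (n - p) else 0
  J <- jac_fn(par)
  jtj <- crossprod(J)
  cov <- tryCatch(solve(jtj), error = function(e) NULL)
  se <- if (!is.null(cov)) {
    sqrt(pmax(sigma2 * diag(cov), 0))
  } else {
    # degenerate direction (e.g. baseline at its bound): per-parameter
    # curvature fallback
    sqrt(pmax(sigma2 / diag(jtj), 0))
  }
  list(converged = TRUE, par = par, se = stats::setNames(se, names(start)),
       deviance = res$deviance)
}

# Starting values from a log-linear regression of (value - plateau guess).
.decay_start <- function(times, values, k_bounds, baseline_bounds) {
  b0 <- max(baseline_bounds[1], min(min(values), baseline_bounds[2]))
  # keep the subtraction strictly positive for the log
  shifted <- (values - b0) / max(1 - b0, 1e-6)
  ok <- shifted > 1e-6
  k0 <- if (sum(ok) >= 2 && stats::sd(times[ok]) > 0) {
    sl <- stats::coef(stats::lm(log(shifted[ok]) ~ times[ok]))[2]
    -as.numeric(sl)
  } else {
    0.1
  }
  if (!is.finite(k0)) k0 <- 0.1
  k0 <- min(max(k0, k_bounds[1] * 2), k_bounds[2] / 2)
  b0 <- min(max(b0 * 0.9, baseline_bounds[1]), baseline_bounds[2])
  list(k = k0, b = b0)
}

#' Goodness-of-fit statistics for a fitted rate
#'
#' The t-statistic is the rate divided by its standard error; the p-value is
#' the one-sided upper-tail Student-t probability with `n_points - 2` degrees
#' of freedom (two fitted parameters), i.e. the probability that a rate of
#' this magnitude would arise if the true rate were zero.
#'
#' @param k_t Fitted rate constant (1/day).
#' @param se_k Standard error of the rate; `se_k = 0` yields an infinite
#'   t-statistic with p-value 0.
#' @param n_points Number of observations used in the fit.
#' @return List with `t_stat` and `p_value`.
#' @export
goodness_stats <- function(k_t, se_k, n_points) {
  if (!is.finite(k_t) || !is.finite(se_k) || se_k < 0) {
    stop("goodness_stats() requires finite k_t and non-negative se_k")
  }
  df <- n_points - 2
  if (df < 1) stop("need at least 3 points for goodness statistics")
  if (se_k == 0) {
    return(list(t_stat = Inf, p_value = 0))
  }
  t_stat <- k_t / se_k
  list(t_stat = t_stat,
       p_value = stats::pt(t_stat, df = df, lower.tail = FALSE))
}

#' Cell-cycle correction of an observed turnover rate
#'
#' Removes the dilution component of protein clearance: `k_deg = k_t - k_div`.
#' Proteins whose observed turnover does not exceed the cell-division rate are
#' flagged division-dominated; their corrected half-life is undefined (NA)
#' because within measurement limits they are cleared by dilution alone.
#'
#' @param k_t Observed turnover rate constant (1/day), positive.
#' @param k_div Cell-division rate constant (1/day), non-negative.
#' @return List of class `corrected_rate` with `k_deg`, `t_half_corr`,
#'   `division_dominated`. Vectorized over `k_t`.
#' @examples
#' correct_kdeg(log(2) / 2.4, log(2) / 51)
#' @export
correct_kdeg <- function(k_t, k_div) {
  if (length(k_div) != 1 || !is.finite(k_div) || k_div < 0) {
    stop("k_div must be a single non-negative finite rate")
  }
  if (any(!is.finite(k_t)) || any(k_t <= 0)) {
    stop("k_t must be positive and finite")
  }
  k_deg <- k_t - k_div
  division_dominated <- k_t <= k_div
  t_half_corr <- ifelse(k_deg > 0, log(2) / k_deg, NA_real_)
  structure(
    list(k_deg = k_deg, t_half_corr = t_half_corr,
         division_dominated = division_dominated),
    class = "corrected_rate"
  )
}

#' @export
print.turnover_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<turnover_fit: failed>\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<turnover_fit> k_t = %.4g /day (se %.3g), baseline = %.3g, R2 = %.3f\n",
    x$k_t, x$se_k, x$baseline, x$r2))
  cat(sprintf("  t = %.3g, p = %.3g, t1/2 = %.3g d, n = %d\n",
              x$t_stat, x$p_value, x$half_life, x$n_points))
  invisible(x)
}
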
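# Bivariate linear detectors of directed information flow: Granger causality
# from nested autoregressions, and Liang's covariance-based information flow.

# Lagged design matrix: rows t = p+1..n, columns x_{t-1}..x_{t-p}.
lag_design <- function(x, p) {
  n <- length(x)
  m <- matrix(0, n - p, p)
  for (k in seq_len(p)) m[, k] <- x[(p + 1 - k):(n - k)]
  m
}

rss_fit <- function(y, X) {
  fit <- .lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    ad_error("rank-deficient regression design (constant or collinear series)",
             "anticipatr_degenerate_input_error")
  }
  sum(fit$residuals^2)
}

#' Bivariate Granger causality F statistics
#'
#' For each direction, fits by ordinary least squares the restricted
#' autoregression of the target on its own `p` lags and the unrestricted
#' model that adds the other series' `p` lags, on the same sample window, and
#' reports the log residual-variance ratio
#' \deqn{F = \ln(\hat\sigma^2_{restricted} / \hat\sigma^2_{unrestricted})}
#' (in nats). Because each equation is univariate, the residual covariance
#' determinants reduce to scalar variances. Inputs are mean-centered and the
#' regressions carry no intercept. The direction with the larger F is the
#' nominal Granger direction of information flow; asymptotic p-values come
#' from the chi-square tail of `n * F` with `p` degrees of freedom (the
#' standard large-sample likelihood-ratio equivalence).
#'
#' @param u,v Numeric series of equal length (`> 2p + 10`).
#' @param p Autoregression order (steps, `>= 1`).
#' @return An object of class `gc_result` with fields `order`, `f_fwd`
#'   (`u` to `v`), `f_rev` (`v` to `u`), `p_fwd`, `p_rev` and `n_effective`.
#' @examples
#' set.seed(1)
#' u <- as.numeric(arima.sim(list(ar = 0.8), 2000))
#' v <- 0.5 * c(0, u[-2000]) + rnorm(2000)
#' granger_f(u, v, p = 2)  # F(u -> v) should dominate
#' @export
granger_f <- function(u, v, p) {
  if (!is_count(p) || p < 1) {
    ad_error("`p` must be a positive integer", "anticipatr_parameter_error")
  }
  n <- length(u)
  if (length(v) != n) ad_error("series must have equal length", "anticipatr_alignment_error")
  if (n <= 2 * p + 10) {
    ad_error("series too short for the requested order", "anticipatr_insufficient_data_error")
  }
  if (stats::var(u) == 0 || stats::var(v) == 0) {
    ad_error("constant input series", "anticipatr_degenerate_input_error")
  }
  u <- u - mean(u)
  v <- v - mean(v)
  Xu <- lag_design(u, p)
  Xv <- lag_design(v, p)
  yu <- u[(p + 1):n]
  yv <- v[(p + 1):n]
  n_eff <- n - p
  f_fwd <- log(rss_fit(yv, Xv) / rss_fit(yv, cbind(Xv, Xu)))
  f_rev <- log(rss_fit(yu, Xu) / rss_fit(yu, cbind(Xu, Xv)))
  structure(
    list(order = as.integer(p), f_fwd = f_fwd, f_rev = f_rev,
         p_fwd = gc_pvalue(max(f_fwd, 0), p, n_eff),
         p_rev = gc_pvalue(max(f_rev, 0), p, n_eff),
         n_effective = n_eff),
    class = "gc_result"
  )
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("<gc_result> order %d, n = %d\n  F fwd %.4g (p = %.3g)   F rev %.4g (p = %.3g)\n",
              x$order, x$n_effective, x$f_fwd, x$p_fwd, x$f_rev, x$p_rev))
  invisible(x)
}

#' Asymptotic p-value for a Granger F statistic
#'
#' Upper tail of the chi-square distribution with `p` degrees of freedom
#' evaluated at `n * f`, using the large-sample equivalence between the log
#' variance-ratio statistic and the likelihood ratio.
#'
#' @param f Log variance-ratio statistic (nats, `>= 0`).
#' @param p Autoregression order (degrees of freedom).
#' @param n Effective sample size (`> p`).
#' @return A p-value in `[0, 1]`.
#' @examples
#' gc_pvalue(0, 5, 1000)    # 1
#' gc_pvalue(0.01, 5, 5000) # small
#' @export
gc_pvalue <- function(f, p, n) {
  stopifnot(f >= 0, p >= 1, n > p)
  stats::pchisq(n * f, df = p, lower.tail = FALSE)
}

#' Select the autoregression order by information criterion
#'
#' Fits the unrestricted bivariate vector autoregression for each order
#' `p = 1..p_max` on a common sample window and evaluates
#' \deqn{AIC(p) = \ln\det\hat\Sigma(p) + 2\,(4p+2)/n}
#' (BIC replaces the 2 with `ln n`), where \eqn{\hat\Sigma(p)} is the 2x2
#' residual covariance. Returns the argmin; when the criterion is strictly
#' decreasing through `p_max` — the saturation seen on long-memory series,
#' where no minimum exists — the largest order is returned with a
#' `saturated` flag set.
#'
#' @param u,v Numeric series of equal length (`> 10 * p_max`).
#' @param p_max Largest order to consider.
#' @param criterion `"AIC"` or `"BIC"`.
#' @return An object of class `var_order` with fields `order`, `saturated`,
#'   `criterion` and `values` (criterion value per order).
#' @export
select_var_order <- function(u, v, p_max = 20, criterion = c("BIC", "AIC")) {
  criterion <- match.arg(criterion)
  if (!is_count(p_max) || p_max < 1) {
    ad_error("`p_max` must be a positive integer", "anticipatr_parameter_error")
  }
  n <- length(u)
  if (length(v) != n) ad_error("series must have equal length", "anticipatr_alignment_error")
  if (n <= 10 * p_max) {
    ad_error("series too short: need length > 10 * p_max", "anticipatr_insufficient_data_error")
  }
  u <- u - mean(u)
  v <- v - mean(v)
  # common estimation window so criteria are comparable across orders
  idx <- (p_max + 1):n
  n_eff <- length(idx)
  Y <- cbind(u[idx], v[idx])
  pen <- if (criterion == "AIC") 2 else log(n_eff)
  vals <- numeric(p_max)
  for (p in seq_len(p_max)) {
    X <- matrix(0, n_eff, 2 * p)
    for (k in seq_len(p)) {
      X[, 2 * k - 1] <- u[idx - k]
      X[, 2 * k] <- v[idx - k]
    }
    res <- .lm.fit(X, Y)$residuals
    sigma <- crossprod(res) / n_eff
    vals[p] <- log(det(sigma)) + pen * (4 * p + 2) / n_eff
  }
  saturated <- all(diff(vals) < 0)
  structure(
    list(order = if (saturated) p_max else which.min(vals),
         saturated = saturated, criterion = criterion, values = vals),
    class = "var_order"
  )
}

#' @export
print.var_order <- function(x, ...) {
  cat(sprintf("<var_order> %s-selected order %d%s (p_max %d)\n", x$criterion,
              x$order, if (x$saturated) " [criterion saturating, no minimum]" else "",
              length(x$values)))
  invisible(x)
}

#' Liang's information flow rate between two series
#'
#' Closed-form maximum-likelihood estimator of the information flow rate for
#' a linear system, built from sample covariances of the two series and
#' their finite-difference derivatives
#' \eqn{\dot u_i = (u_{i+1} - u_i)/\Delta t}:
#' \deqn{T_{V \to U} = \frac{C_{UU} C_{UV} C_{V\dot U} - C_{UV}^2 C_{U \dot U}}
#'       {C_{UU}^2 C_{VV} - C_{UU} C_{UV}^2}.}
#' A nonzero \eqn{|T_{V \to U}|} indicates that `v` is causal to `u`; as a
#' direction call the two magnitudes are compared. The ratio is invariant
#' under separate affine rescaling of either input and insensitive to the
#' covariance normalization.
#'
#' @param u,v Numeric series of equal length (`>= 3`).
#' @param dt Time step in seconds (sets the units of T, inverse time).
#' @return An object of class `liang_t_result` with fields `t_fwd`
#'   (`u` to `v`), `t_rev` (`v` to `u`) and `dt`.
#' @export
liang_t <- function(u, v, dt = 1) {
  n <- length(u)
  if (length(v) != n) ad_error("series must have equal length", "anticipatr_alignment_error")
  if (n < 3L) ad_error("need at least 3 samples", "anticipatr_insufficient_data_error")
  if (!is_number(dt) || dt <= 0) ad_error("`dt` must be positive", "anticipatr_parameter_error")
  if (stats::var(u) == 0 || stats::var(v) == 0) {
    ad_error("zero-variance input: Liang's T denominator vanishes",
             "anticipatr_degenerate_input_error")
  }
  du <- diff(u) / dt
  dv <- diff(v) / dt
  uu <- u[-n]
  vv <- v[-n]
  flow_into <- function(a, b, da) {
    # T_{b -> a}: flow from b into a, using a's derivative
    caa <- stats::cov(a, a); cab <- stats::cov(a, b); cbb <- stats::cov(b, b)
    cbda <- stats::cov(b, da); cada <- stats::cov(a, da)
    (caa * cab * cbda - cab^2 * cada) / (caa^2 * cbb - caa * cab^2)
  }
  structure(
    list(t_fwd = flow_into(vv, uu, dv), t_rev = flow_into(uu, vv, du), dt = dt),
    class = "liang_t_result"
  )
}

#' @export
print.liang_t_result <- function(x, ...) {
  cat(sprintf("<liang_t_result> T fwd %.4g, T rev %.4g (per second, dt = %.4g s)\n",
              x$t_fwd, x$t_rev, x$dt))
  invisible(x)
}
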
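#' Plug-in mutual information between two aligned symbol series
#'
#' Computes the plug-in (maximum-likelihood histogram) estimate of the mutual
#' information in bits,
#' \deqn{I(A;B) = \sum_{a,b} p(a,b) \log_2 \frac{p(a,b)}{p(a)\,p(b)},}
#' with probabilities taken from the empirical joint histogram and the
#' convention \eqn{0 \log 0 = 0}. The estimate is nonnegative by construction
#' and bounded above by the smaller marginal entropy.
#'
#' @param a,b [symbol_series()] objects (or plain integer vectors) of equal
#'   length, sample-aligned.
#' @return Mutual information in bits (a single number).
#' @examples
#' s <- symbol_series(rep(0:3, 50), bits = 2)
#' mutual_information(s, s)  # = H(s) = 2 bits
#' @export
mutual_information <- function(a, b) {
  a <- as_symbol_series(a)
  b <- as_symbol_series(b)
  if (length(a$symbols) != length(b$symbols)) {
    ad_error("series must have equal length", "anticipatr_alignment_error")
  }
  if (length(a$symbols) < 2L) {
    ad_error("need at least 2 aligned samples", "anticipatr_insufficient_data_error")
  }
  mi_int(a$symbols, b$symbols, 2^a$bits, 2^b$bits)
}

# Fast path on 0-based integer vectors with known alphabet sizes.
mi_int <- function(a, b, ka, kb) {
  n <- length(a)
  p <- tabulate(a * kb + b + 1L, ka * kb) / n
  pa <- rep(tabulate(a + 1L, ka) / n, each = kb)
  pb <- rep(tabulate(b + 1L, kb) / n, times = ka)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / (pa[nz] * pb[nz])))
}

#' Time-lag mutual information at a single lag
#'
#' Evaluates \eqn{I(U, V, \delta t)} with \eqn{\delta t = j \Delta t}: the
#' mutual information between `u` shifted `j` steps ahead and `v`, i.e.
#' between the pairs \eqn{(u_{t+j}, v_t)} over their valid overlap (edges are
#' truncated; there is no wraparound). Under this pairing a peak at positive
#' lag means the series `v` leads `u` in time, and a peak at negative lag
#' means `u` leads.
#'
#' @param u,v [symbol_series()] objects of equal length.
#' @param lag_steps Integer lag `j`, with `|j| <= n - 2`.
#' @return Mutual information in bits at that lag.
#' @examples
#' u <- symbol_series(rep(0:3, 25), bits = 2)
#' tlmi(u, u, 4)  # the 4-periodic sequence realigns with itself
#' @export
tlmi <- function(u, v, lag_steps) {
  u <- as_symbol_series(u)
  v <- as_symbol_series(v)
  n <- length(u$symbols)
  if (length(v$symbols) != n) {
    ad_error("series must have equal length", "anticipatr_alignment_error")
  }
  if (!is_count(lag_steps) || abs(lag_steps) > n - 2L) {
    ad_error(sprintf("|lag_steps| must be at most n - 2 = %d", n - 2L),
             "anticipatr_lag_range_error")
  }
  w <- lag_overlap(n, lag_steps)
  mi_int(u$symbols[w$u], v$symbols[w$v], 2^u$bits, 2^v$bits)
}

#' Time-lag mutual information curve over a symmetric lag window
#'
#' Evaluates [tlmi()] on every integer lag in
#' `[-max_lag_s/dt, +max_lag_s/dt]`. The resulting curve is the package's
#' basic descriptor of the temporal relation between two series: for a cross
#' curve, the lag of the maximum says which series leads and by how much, and
#' its height (relative to the auto curves at zero lag) measures interaction
#' strength.
#'
#' @param u,v [symbol_series()] objects of equal length and time step.
#' @param max_lag_s Half-width of the lag window, seconds (at least one step).
#' @param kind `"auto"` or `"cross"`; inferred when `NULL` (auto when `u` and
#'   `v` hold identical symbols).
#' @return An object of class `tlmi_curve` with fields `lag_steps`, `lag_s`,
#'   `values_bits`, `kind` and `time_step_s`.
#' @export
tlmi_curve <- function(u, v, max_lag_s, kind = NULL) {
  u <- as_symbol_series(u)
  v <- as_symbol_series(v)
  dt <- u$time_step_s
  if (max_lag_s < dt) {
    ad_error("`max_lag_s` must be at least one time step", "anticipatr_lag_range_error")
  }
  jmax <- floor(max_lag_s / dt + 1e-9)
  n <- length(u$symbols)
  if (jmax > n - 2L) {
    ad_error("lag window exceeds series length", "anticipatr_lag_range_error")
  }
  if (is.null(kind)) kind <- if (identical(u$symbols, v$symbols)) "auto" else "cross"
  lags <- seq.int(-jmax, jmax)
  ku <- 2^u$bits; kv <- 2^v$bits
  vals <- vapply(lags, function(j) {
    w <- lag_overlap(n, j)
    mi_int(u$symbols[w$u], v$symbols[w$v], ku, kv)
  }, numeric(1))
  structure(
    list(lag_steps = lags, lag_s = lags * dt, values_bits = vals,
         kind = match.arg(kind, c("auto", "cross")), time_step_s = dt),
    class = "tlmi_curve"
  )
}

#' @export
print.tlmi_curve <- function(x, ...) {
  i <- which.max(x$values_bits)
  cat(sprintf("<tlmi_curve> %s, lags %+.3g..%+.3g s, max %.4g bits at %+.3g s\n",
              x$kind, min(x$lag_s), max(x$lag_s), x$values_bits[i], x$lag_s[i]))
  invisible(x)
}

#' @export
as.data.frame.tlmi_curve <- function(x, ...) {
  data.frame(lag_s = x$lag_s, bits = x$values_bits)
}

#' Export a TLMI curve as two-column CSV
#'
#' @param curve A [tlmi_curve()].
#' @param path Output path; columns are `lag_s` and `bits`.
#' @return Invisibly, `path`.
#' @export
write_tlmi_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Peak of a curve with ties broken toward the smallest |lag|, then toward the
# negative lag. The bias is deliberate: prefer "no lead" over a spurious lead.
curve_peak <- function(curve) {
  v <- curve$values_bits
  cand <- which(v == max(v))
  if (length(cand) > 1L) {
    al <- abs(curve$lag_steps[cand])
    cand <- cand[al == min(al)]
    if (length(cand) > 1L) cand <- cand[which.min(curve$lag_steps[cand])]
  }
  cand[1]
}

#' Half-decay time of an auto-TLMI curve
#'
#' First nonnegative lag at which the auto curve drops below half of its
#' zero-lag value, in seconds; a measure of the memory time scale of the
#' series. Returns `NA` (with a warning) if the curve never drops below half
#' within its lag window.
#'
#' @param curve A [tlmi_curve()] evaluated on a grid containing lag 0.
#' @return Half-decay time in seconds.
#' @export
half_decay_time <- function(curve) {
  nn <- curve$lag_steps >= 0L
  lags <- curve$lag_s[nn]
  vals <- curve$values_bits[nn]
  o <- order(lags)
  lags <- lags[o]; vals <- vals[o]
  below <- which(vals < vals[1] / 2)
  if (length(below) == 0L) {
    warning("auto-TLMI does not reach half its zero-lag value within the window")
    return(NA_real_)
  }
  lags[below[1]]
}

#' Peak and decay summary of a cross-TLMI curve
#'
#' Summarizes a cross curve against the two auto curves: the global maximum
#' (ties broken toward the smallest absolute lag, then toward negative lag),
#' its height normalized by the mean of the two auto-TLMI zero-lag values,
#' and the half-decay time of agent 0's auto curve. The normalized height is
#' independent of the bit depth used in the discretization and measures the
#' interaction strength.
#'
#' @param cross Cross [tlmi_curve()] between the two agents.
#' @param auto0,auto1 Auto [tlmi_curve()]s of agents 0 and 1 on the same lag
#'   grid as `cross`.
#' @return An object of class `peak_summary` with `peak_lag_s`,
#'   `peak_height_bits`, `normalized_height` and `half_decay_s`.
#' @export
peak_summary <- function(cross, auto0, auto1) {
  for (cu in list(cross, auto0, auto1)) {
    if (!inherits(cu, "tlmi_curve") || length(cu$values_bits) == 0L) {
      ad_error("inputs must be non-empty tlmi_curve objects", "anticipatr_input_error")
    }
  }
  if (!identical(cross$lag_steps, auto0$lag_steps) ||
      !identical(cross$lag_steps, auto1$lag_steps)) {
    ad_error("curves must share the same lag grid", "anticipatr_input_error")
  }
  i <- curve_peak(cross)
  z0 <- auto0$values_bits[auto0$lag_steps == 0L]
  z1 <- auto1$values_bits[auto1$lag_steps == 0L]
  ref <- mean(c(z0, z1))
  structure(
    list(
      peak_lag_s = cross$lag_s[i],
      peak_height_bits = cross$values_bits[i],
      normalized_height = if (ref > 0) cross$values_bits[i] / ref else 0,
      half_decay_s = suppressWarnings(half_decay_time(auto0))
    ),
    class = "peak_summary"
  )
}

#' @export
print.peak_summary <- function(x, ...) {
  cat(sprintf("<peak_summary> peak %+.3g s, height %.4g bits (%.3g of auto), auto half-decay %.3g s\n",
              x$peak_lag_s, x$peak_height_bits, x$normalized_height, x$half_decay_s))
  invisible(x)
}

#' Permissible joint-state count for transfer entropy
#'
#' Number of joint states entering the plug-in transfer-entropy histogram for
#' an alphabet of `2^bits` symbols and history length `h`:
#' `(2^bits)^(h+1)`. When this approaches or exceeds the series length, the
#' plug-in estimate is strongly biased; [transfer_entropy()] warns in that
#' regime.
#'
#' @param bits Bit depth of the discretization.
#' @param h History length in steps.
#' @return The state count, as a double.
#' @examples
#' te_state_count(2, 8)  # 4^9 = 262144
#' @export
te_state_count <- function(bits, h) {
  (2^bits)^(h + 1)
}

#' Transfer entropy between two symbol series
#'
#' Plug-in transfer entropy with equal source and target history lengths
#' `h`, in the Schreiber form
#' \deqn{T_{U \to V}(h) = H(V_t \mid V_{t-1}^{(h)}) -
#'       H(V_t \mid V_{t-1}^{(h)}, U_{t-1}^{(h)}),}
#' the reduction in the conditional entropy of the target's next state from
#' additionally conditioning on the source's history. Both directions are
#' computed, together with the net flow `delta_bits = te_fwd - te_rev`; a
#' positive net flow indicates net information transfer from `src` to `tgt`.
#'
#' All conditional entropies are plug-in estimates over empirical joint
#' histograms, so both directed values are nonnegative.
#'
#' @param src,tgt [symbol_series()] objects of equal length.
#' @param h History length in steps (`h >= 1`).
#' @return An object of class `te_result` with fields `h`, `te_fwd_bits`
#'   (`src` to `tgt`), `te_rev_bits`, `delta_bits` and `bits`.
#' @examples
#' u <- symbol_series(sample(0:1, 300, TRUE), bits = 1)
#' v <- symbol_series(c(0L, u$symbols[-300]), bits = 1)
#' transfer_entropy(u, v, h = 1)  # u drives v with one step of delay
#' @export
transfer_entropy <- function(src, tgt, h) {
  src <- as_symbol_series(src)
  tgt <- as_symbol_series(tgt)
  if (!is_count(h) || h < 1) {
    ad_error("`h` must be a positive integer", "anticipatr_parameter_error")
  }
  n <- length(src$symbols)
  if (length(tgt$symbols) != n) {
    ad_error("series must have equal length", "anticipatr_alignment_error")
  }
  if (n < h + 2L) {
    ad_error("series shorter than history length + 2", "anticipatr_insufficient_data_error")
  }
  guard <- te_state_count(max(src$bits, tgt$bits), h)
  if (n <= guard) {
    warning(sprintf(
      "series length %d does not exceed the %g permissible joint states at h = %d; plug-in TE will be biased",
      n, guard, h
    ))
  }
  fwd <- te_directed(src$symbols, tgt$symbols, h)
  rev <- te_directed(tgt$symbols, src$symbols, h)
  structure(
    list(h = as.integer(h), te_fwd_bits = fwd, te_rev_bits = rev,
         delta_bits = fwd - rev, bits = max(src$bits, tgt$bits)),
    class = "te_result"
  )
}

# T_{src -> tgt}(h) from 0-based integer vectors.
te_directed <- function(src, tgt, h) {
  n <- length(src)
  idx <- (h + 1L):n
  hist_of <- function(x) {
    m <- matrix(0L, length(idx), h)
    for (k in seq_len(h)) m[, k] <- x[idx - k]
    m
  }
  th <- joint_codes(hist_of(tgt))               # target history
  thu <- joint_codes(cbind(th, joint_codes(hist_of(src))))  # + source history
  vt <- tgt[idx]
  h_cond <- function(past) {
    entropy_codes(joint_codes(cbind(past, vt))) - entropy_codes(past)
  }
  h_cond(th) - h_cond(thu)
}

#' @export
print.te_result <- function(x, ...) {
  cat(sprintf("<te_result> h = %d (%d bit): fwd %.4g, rev %.4g, net %+.4g bits\n",
              x$h, x$bits, x$te_fwd_bits, x$te_rev_bits, x$delta_bits))
  invisible(x)
}
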
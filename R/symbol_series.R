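#' Discretized integer-state series
#'
#' A `symbol_series` holds an integer-valued state sequence together with its
#' bit depth `bits` (alphabet size `2^bits`) and the sampling interval in
#' seconds. It is the common currency of all information-theoretic estimators
#' in the package: positions are reduced to symbols first, and entropies and
#' mutual information are then plug-in estimates over the empirical symbol
#' histograms.
#'
#' @param symbols Integer vector of states, each in `[0, 2^bits)`.
#' @param bits Bit depth (alphabet size is `2^bits`).
#' @param time_step_s Seconds per sample; must be positive.
#'
#' @return An object of class `symbol_series` with fields `symbols`, `bits`
#'   and `time_step_s`.
#' @examples
#' symbol_series(c(0L, 1L, 2L, 3L), bits = 2, time_step_s = 1 / 30)
#' @export
symbol_series <- function(symbols, bits, time_step_s = 1 / 30) {
  if (!is_count(bits) || bits < 1) {
    ad_error("`bits` must be a positive integer", "anticipatr_parameter_error")
  }
  if (!is_number(time_step_s) || time_step_s <= 0) {
    ad_error("`time_step_s` must be a positive number", "anticipatr_parameter_error")
  }
  symbols <- as.integer(symbols)
  if (length(symbols) < 1L || anyNA(symbols)) {
    ad_error("`symbols` must be a non-empty integer vector without NAs",
             "anticipatr_insufficient_data_error")
  }
  if (any(symbols < 0L) || any(symbols >= 2^bits)) {
    ad_error(sprintf("symbols must lie in [0, %d) for bits = %d", 2^bits, bits),
             "anticipatr_parameter_error")
  }
  structure(
    list(symbols = symbols, bits = as.integer(bits), time_step_s = time_step_s),
    class = "symbol_series"
  )
}

#' @export
print.symbol_series <- function(x, ...) {
  cat(sprintf("<symbol_series> %d samples, %d bit (%d states), dt = %.6g s\n",
              length(x$symbols), x$bits, 2^x$bits, x$time_step_s))
  invisible(x)
}

#' @export
length.symbol_series <- function(x) length(x$symbols)

as_symbol_series <- function(x, bits = NULL, time_step_s = 1 / 30) {
  if (inherits(x, "symbol_series")) return(x)
  if (is.null(bits)) bits <- max(1L, ceiling(log2(max(x) + 1)))
  symbol_series(x, bits = bits, time_step_s = time_step_s)
}

#' Discretize a real-valued series over its observed range
#'
#' Equal-width binning of a continuous series into `2^bits` states spanning
#' the observed data range. This is the discretization used when analyzing
#' simulated signals that have no physical span (the tank-anchored
#' counterpart for positions is [discretize_x()]).
#'
#' @param x Numeric vector.
#' @param bits Bit depth; the alphabet has `2^bits` equal-width bins.
#' @param time_step_s Seconds per sample, attached to the result.
#' @return A [symbol_series()].
#' @examples
#' discretize_range(sin(seq(0, 10, by = 0.01)), bits = 4, time_step_s = 0.01)
#' @export
discretize_range <- function(x, bits, time_step_s = 1 / 30) {
  if (!is_count(bits) || bits < 1 || bits > 16) {
    ad_error("`bits` must be an integer in [1, 16]", "anticipatr_resolution_error")
  }
  r <- range(x)
  if (r[1] == r[2]) {
    return(symbol_series(rep(0L, length(x)), bits = bits, time_step_s = time_step_s))
  }
  k <- 2^bits
  s <- floor((x - r[1]) / ((r[2] - r[1]) / k))
  s[s >= k] <- k - 1L
  symbol_series(as.integer(s), bits = bits, time_step_s = time_step_s)
}
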
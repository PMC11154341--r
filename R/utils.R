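# Internal helpers shared across modules.

# Classed error, so callers can distinguish failure modes programmatically.
ad_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "anticipatr_error"), call = call))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Lagged-overlap index windows for pairing u[t + j] with v[t] without wraparound.
lag_overlap <- function(n, j) {
  if (j >= 0) list(u = (1 + j):n, v = 1:(n - j)) else list(u = 1:(n + j), v = (1 - j):n)
}

# Dense integer codes (1-based) for joint symbol states; rows of `m` are samples.
joint_codes <- function(m) {
  key <- do.call(paste, c(as.data.frame(m), sep = "\r"))
  match(key, unique(key))
}

# Plug-in Shannon entropy in bits from 1-based integer codes.
entropy_codes <- function(codes) {
  p <- tabulate(codes)
  p <- p[p > 0] / length(codes)
  -sum(p * log2(p))
}
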
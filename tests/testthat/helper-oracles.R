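# Independent brute-force oracles, deliberately written as direct double sums
# over explicit joint tables rather than reusing any package internals.

mi_oracle <- function(a, b) {
  n <- length(a)
  total <- 0
  for (x in unique(a)) {
    for (y in unique(b)) {
      pxy <- sum(a == x & b == y) / n
      if (pxy > 0) {
        px <- sum(a == x) / n
        py <- sum(b == y) / n
        total <- total + pxy * log2(pxy / (px * py))
      }
    }
  }
  total
}

entropy_oracle <- function(keys) {
  n <- length(keys)
  total <- 0
  for (k in unique(keys)) {
    p <- sum(keys == k) / n
    total <- total - p * log2(p)
  }
  total
}

# H(x | past) via the chain rule on explicit key strings
cond_entropy_oracle <- function(x, past) {
  entropy_oracle(paste(past, x)) - entropy_oracle(past)
}

te_oracle <- function(src, tgt, h) {
  n <- length(src)
  idx <- (h + 1):n
  key_of <- function(v, i) paste(v[(i - h):(i - 1)], collapse = ",")
  th <- vapply(idx, function(i) key_of(tgt, i), character(1))
  sh <- vapply(idx, function(i) key_of(src, i), character(1))
  vt <- tgt[idx]
  cond_entropy_oracle(vt, th) - cond_entropy_oracle(vt, paste(th, sh))
}

ar1_series <- function(n, phi, sd = 1) {
  as.numeric(stats::filter(stats::rnorm(n, sd = sd), phi, method = "recursive"))
}

# v driven by u with one step of delay: v_t = phi v_{t-1} + beta u_{t-1} + e_t
coupled_ar <- function(n, phi = 0.9, beta = 0.5) {
  u <- ar1_series(n, 0.9)
  v <- as.numeric(stats::filter(c(0, beta * u[-n]) + stats::rnorm(n), phi,
                                method = "recursive"))
  list(u = u, v = v)
}

random_symbols <- function(n, bits, dt = 1 / 30) {
  symbol_series(sample(0:(2^bits - 1), n, replace = TRUE), bits = bits,
                time_step_s = dt)
}
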
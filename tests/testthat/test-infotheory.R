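test_that("plug-in MI matches closed forms and the enumeration oracle", {
  # a uniformly occupied 2-bit series shares exactly its own 2 bits with itself
  s <- symbol_series(rep(0:3, 75), bits = 2)
  expect_equal(mutual_information(s, s), 2, tolerance = 1e-12)

  # independent uniform sequences share (almost) nothing
  set.seed(3)
  a <- random_symbols(20000, 2)
  b <- random_symbols(20000, 2)
  expect_lt(mutual_information(a, b), 0.01)

  # exact agreement with a brute-force double sum over the joint histogram
  set.seed(4)
  for (bits in c(1, 2)) {
    u <- random_symbols(100, bits)
    v <- random_symbols(100, bits)
    expect_equal(mutual_information(u, v), mi_oracle(u$symbols, v$symbols),
                 tolerance = 1e-12)
  }

  expect_error(mutual_information(random_symbols(10, 1), random_symbols(11, 1)),
               class = "anticipatr_alignment_error")
})

test_that("MI is nonnegative and bounded by the smaller marginal entropy", {
  set.seed(5)
  for (i in 1:20) {
    u <- random_symbols(200, sample(1:3, 1))
    v <- random_symbols(200, sample(1:3, 1))
    m <- mutual_information(u, v)
    ha <- entropy_oracle(u$symbols)
    hb <- entropy_oracle(v$symbols)
    expect_gte(m, 0)
    expect_lte(m, min(ha, hb) + 1e-12)
  }
})

test_that("tlmi locates a pure delay and respects the lag pairing", {
  # v is a 3-step-delayed copy of u: u leads, so the peak of I(u_{t+j}, v_t)
  # sits at j = -3; swapping the arguments mirrors it to +3
  set.seed(6)
  n <- 400
  u <- random_symbols(n, 2)
  v <- symbol_series(c(u$symbols[1:3], u$symbols[1:(n - 3)]), bits = 2)
  lags <- -6:6
  cu <- vapply(lags, function(j) tlmi(u, v, j), numeric(1))
  expect_equal(lags[which.max(cu)], -3)
  cv <- vapply(lags, function(j) tlmi(v, u, j), numeric(1))
  expect_equal(lags[which.max(cv)], 3)

  # auto case peaks at zero
  ca <- vapply(lags, function(j) tlmi(u, u, j), numeric(1))
  expect_equal(lags[which.max(ca)], 0)

  expect_error(tlmi(u, v, n), class = "anticipatr_lag_range_error")
})

test_that("tlmi on matched overlap windows is symmetric under swap + negation", {
  set.seed(8)
  u <- random_symbols(300, 2)
  v <- random_symbols(300, 2)
  for (j in c(-7, -1, 0, 2, 9)) {
    expect_equal(tlmi(u, v, j), tlmi(v, u, -j), tolerance = 1e-14)
  }
})

test_that("tlmi_curve: auto zero-lag value is the entropy; constants vanish", {
  set.seed(9)
  u <- random_symbols(500, 2)
  cur <- tlmi_curve(u, u, max_lag_s = 0.5)
  expect_equal(cur$kind, "auto")
  expect_equal(cur$values_bits[cur$lag_steps == 0],
               entropy_oracle(u$symbols), tolerance = 1e-12)
  expect_true(all(cur$values_bits >= 0))
  expect_equal(cur$lag_steps, -rev(cur$lag_steps))  # symmetric grid

  const <- symbol_series(rep(1L, 200), bits = 2)
  expect_true(all(tlmi_curve(const, const, 0.5)$values_bits == 0))

  # independent pair: near-flat curve close to zero
  v <- random_symbols(5000, 2)
  w <- random_symbols(5000, 2)
  expect_lt(max(tlmi_curve(v, w, 0.2)$values_bits), 0.05)
})

test_that("peak_summary applies the tie-break and half-decay definitions", {
  mk <- function(lags, vals, dt = 1) {
    structure(list(lag_steps = as.integer(lags), lag_s = lags * dt,
                   values_bits = vals, kind = "cross", time_step_s = dt),
              class = "tlmi_curve")
  }
  cross <- mk(-1:2, c(0.1, 0.3, 0.3, 0.1))
  auto <- mk(-1:2, c(0.6, 1.0, 0.6, 0.45))
  ps <- peak_summary(cross, auto, auto)
  expect_equal(ps$peak_lag_s, 0)          # tie resolved toward |lag| minimum
  expect_equal(ps$peak_height_bits, 0.3)
  expect_equal(ps$normalized_height, 0.3 / 1.0)
  expect_equal(ps$half_decay_s, 2)        # first value below 0.5 is at lag 2

  # a summary shaped like a report row: peak at -0.83 s, ratio 0.22
  dt <- 1 / 30
  lags <- -60:60
  vals <- 0.22 * exp(-(lags * dt + 0.83)^2)
  cross2 <- mk(lags, vals, dt)
  auto2 <- mk(lags, exp(-abs(lags * dt) / 0.8), dt)
  ps2 <- peak_summary(cross2, auto2, auto2)
  expect_equal(ps2$peak_lag_s, -0.83, tolerance = 0.02)
  expect_equal(ps2$normalized_height, 0.22, tolerance = 1e-4)

  expect_error(peak_summary(cross, mk(-2:1, rep(1, 4)), auto),
               class = "anticipatr_input_error")
})

test_that("transfer entropy recovers a pure one-step drive", {
  set.seed(10)
  n <- 2000
  u <- symbol_series(sample(0:1, n, TRUE), bits = 1)
  v <- symbol_series(c(0L, u$symbols[-n]), bits = 1)
  r <- transfer_entropy(u, v, h = 1)
  expect_equal(r$te_fwd_bits, 1, tolerance = 0.05)  # all of v's 1 bit comes from u
  expect_equal(r$te_rev_bits, 0, tolerance = 0.05)  # u is iid
  expect_equal(r$delta_bits, r$te_fwd_bits - r$te_rev_bits)
})

test_that("transfer entropy matches the enumeration oracle exactly", {
  set.seed(11)
  u <- symbol_series(sample(0:1, 200, TRUE), bits = 1)
  v <- symbol_series(sample(0:1, 200, TRUE), bits = 1)
  r <- suppressWarnings(transfer_entropy(u, v, h = 2))
  expect_equal(r$te_fwd_bits, te_oracle(u$symbols, v$symbols, 2), tolerance = 1e-12)
  expect_equal(r$te_rev_bits, te_oracle(v$symbols, u$symbols, 2), tolerance = 1e-12)
  expect_gte(r$te_fwd_bits, 0)
  expect_gte(r$te_rev_bits, 0)

  a <- random_symbols(150, 2)
  b <- random_symbols(150, 2)
  r2 <- suppressWarnings(transfer_entropy(a, b, h = 1))
  expect_equal(r2$te_fwd_bits, te_oracle(a$symbols, b$symbols, 1), tolerance = 1e-12)
})

test_that("transfer entropy guards its parameters and state count", {
  u <- random_symbols(50, 2)
  expect_error(transfer_entropy(u, u, h = 0), class = "anticipatr_parameter_error")
  expect_error(transfer_entropy(u, random_symbols(49, 2), 1),
               class = "anticipatr_alignment_error")
  expect_error(transfer_entropy(random_symbols(3, 1), random_symbols(3, 1), h = 4),
               class = "anticipatr_insufficient_data_error")
  # the permissible-state guard grows as (2^bits)^(h+1)
  expect_identical(te_state_count(2, 8), 4^9)
  expect_identical(te_state_count(1, 1), 4)
  expect_warning(transfer_entropy(u, u, h = 4), "biased")
})
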
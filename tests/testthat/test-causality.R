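test_that("granger_f recovers the direction of a unidirectional coupling", {
  set.seed(20)
  hits <- 0
  for (s in 1:20) {
    sim <- coupled_ar(4000)
    g <- granger_f(sim$u, sim$v, p = 2)
    hits <- hits + (g$f_fwd > g$f_rev && g$p_fwd < 0.05)
  }
  expect_gte(hits, 19)
})

test_that("granger_f stays near zero for independent white noise", {
  set.seed(21)
  p <- 5; n <- 4000
  small <- 0
  for (s in 1:20) {
    g <- granger_f(rnorm(n), rnorm(n), p)
    small <- small + (g$f_fwd < 3 * p / n && g$f_rev < 3 * p / n)
  }
  expect_gte(small, 18)
})

test_that("nested OLS makes both F statistics nonnegative", {
  set.seed(22)
  for (i in 1:10) {
    n <- 500
    u <- ar1_series(n, runif(1, -0.5, 0.9))
    v <- 0.7 * u + rnorm(n)   # strong instantaneous correlation
    g <- granger_f(u, v, p = sample(1:6, 1))
    expect_gte(g$f_fwd, -1e-10)
    expect_gte(g$f_rev, -1e-10)
    expect_true(g$p_fwd >= 0 && g$p_fwd <= 1)
  }
  expect_error(granger_f(rep(1, 100), rnorm(100), 2),
               class = "anticipatr_degenerate_input_error")
})

test_that("gc_pvalue follows the chi-square tail", {
  expect_equal(gc_pvalue(0, 5, 1000), 1)
  expect_lt(gc_pvalue(100 / 2000, 10, 2000), 1e-10)  # n * f = 100 at p = 10
  expect_equal(gc_pvalue(0.01, 3, 500), pchisq(5, 3, lower.tail = FALSE))
})

test_that("order selection finds white-noise and VAR(2) orders, flags saturation", {
  set.seed(23)
  bic1 <- 0
  for (s in 1:20) {
    sel <- select_var_order(rnorm(3000), rnorm(3000), p_max = 10)
    bic1 <- bic1 + (sel$order == 1)
  }
  expect_gte(bic1, 18)

  got2 <- 0
  for (s in 1:10) {
    n <- 5000
    e1 <- rnorm(n); e2 <- rnorm(n)
    u <- numeric(n); v <- numeric(n)
    for (i in 3:n) {
      u[i] <- 0.5 * u[i - 1] - 0.4 * u[i - 2] + 0.3 * v[i - 2] + e1[i]
      v[i] <- 0.4 * v[i - 1] + 0.35 * u[i - 2] - 0.3 * v[i - 2] + e2[i]
    }
    got2 <- got2 + (select_var_order(u, v, p_max = 8)$order == 2)
  }
  expect_gte(got2, 9)

  # a near-unit-root MA input has a slowly decaying infinite AR form, so the
  # criterion keeps improving through p_max with no minimum
  set.seed(24)
  ma1 <- function(n) as.numeric(stats::filter(rnorm(n), c(1, 0.95),
                                              method = "convolution", sides = 1))[-1]
  sel <- select_var_order(ma1(6000), ma1(6000), p_max = 6)
  expect_true(sel$saturated)
  expect_equal(sel$order, 6)

  expect_error(select_var_order(rnorm(50), rnorm(50), p_max = 10),
               class = "anticipatr_insufficient_data_error")
})

test_that("liang_t is scale invariant and vanishes for independent noise", {
  set.seed(25)
  u <- ar1_series(1000, 0.8)
  v <- ar1_series(1000, 0.6)
  base <- liang_t(u, v, dt = 0.1)
  resc <- liang_t(3.7 * u, -0.2 * v, dt = 0.1)
  expect_equal(resc$t_fwd, base$t_fwd, tolerance = 1e-10)
  expect_equal(resc$t_rev, base$t_rev, tolerance = 1e-10)

  small <- 0
  for (s in 1:20) {
    n <- 4000
    r <- liang_t(rnorm(n), rnorm(n), dt = 1)
    small <- small + (abs(r$t_fwd) < 5 / sqrt(n) && abs(r$t_rev) < 5 / sqrt(n))
  }
  expect_gte(small, 18)

  expect_error(liang_t(rep(2, 100), rnorm(100)),
               class = "anticipatr_degenerate_input_error")
  expect_error(liang_t(1:2, 1:2), class = "anticipatr_insufficient_data_error")
})
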
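test_that("a well-formed CSV round-trips through read/write exactly", {
  set.seed(1)
  n <- 50
  pair <- trajectory_pair(
    x0 = runif(n, 0, 216), y0 = runif(n, 0, 140),
    x1 = runif(n, 0, 216), y1 = runif(n, 0, 140)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_pair(pair, path)
  back <- read_trajectory_pair(path)
  expect_equal(back$n_samples, n)
  expect_equal(back$x0, pair$x0, tolerance = 1e-9)
  expect_equal(back$y0, pair$y0, tolerance = 1e-9)
  expect_equal(back$x1, pair$x1, tolerance = 1e-9)
  expect_equal(back$y1, pair$y1, tolerance = 1e-9)
  expect_equal(back$time_step_s, pair$time_step_s, tolerance = 1e-9)
})

test_that("read_trajectory_pair validates shape and timing", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(t = (0:4) / 30, x0 = 1:5, y0 = 1:5, x1 = 1:5, y1 = 1:5)
  write.csv(df, path, row.names = FALSE)
  expect_equal(read_trajectory_pair(path)$n_samples, 5)

  write.csv(df[, setdiff(names(df), "y1")], path, row.names = FALSE)
  expect_error(read_trajectory_pair(path), "y1", class = "anticipatr_format_error")

  df2 <- df; df2$t[3] <- df2$t[2]     # repeated timestamp
  write.csv(df2, path, row.names = FALSE)
  expect_error(read_trajectory_pair(path), class = "anticipatr_timing_error")

  df3 <- df; df3$t[4] <- df3$t[4] + 0.01  # uneven spacing
  write.csv(df3, path, row.names = FALSE)
  expect_error(read_trajectory_pair(path), class = "anticipatr_timing_error")

  write.csv(df[1, ], path, row.names = FALSE)
  expect_error(read_trajectory_pair(path), class = "anticipatr_insufficient_data_error")
})

test_that("writing a degenerate pair or unwritable path errors", {
  pair <- trajectory_pair(x0 = c(1, 2), y0 = c(1, 2), x1 = c(1, 2), y1 = c(1, 2))
  broken <- pair
  broken$n_samples <- 1L
  expect_error(write_trajectory_pair(broken, tempfile()),
               class = "anticipatr_insufficient_data_error")
  expect_error(write_trajectory_pair(pair, "/nonexistent-dir/x.csv"),
               class = "anticipatr_io_error")
})

test_that("out-of-span x positions are clamped with a reported count", {
  expect_message(
    pair <- trajectory_pair(x0 = c(-3, 10, 220), y0 = rep(100, 3),
                            x1 = rep(10, 3), y1 = rep(40, 3)),
    "clamped 2"
  )
  expect_equal(pair$x0, c(0, 10, 216))
  expect_equal(pair$n_clamped, 2)
})

test_that("discretize_x bins the physical span with edge clamping", {
  s <- discretize_x(c(0, 107.9, 108, 162, 216, -0.4, 300), bits = 2)
  expect_equal(s$symbols, c(0L, 1L, 2L, 3L, 3L, 0L, 3L))
  expect_equal(s$bits, 2L)
  expect_error(discretize_x(1:10, bits = 17), class = "anticipatr_resolution_error")
})

test_that("discretize_x is monotone in position", {
  set.seed(7)
  for (bits in c(1, 2, 4)) {
    x <- sort(runif(500, -10, 226))
    s <- discretize_x(x, bits)$symbols
    expect_true(all(diff(s) >= 0))
  }
})

test_that("channel_state maps the divider and both channels per the tie rule", {
  s <- channel_state(c(80, 10, 70, 70.001), wall_y_mm = 70)
  expect_equal(s$symbols, c(0L, 1L, 1L, 0L))
  expect_equal(s$bits, 1L)
  # both channels visited => alphabet is exactly {0, 1}
  set.seed(2)
  y <- runif(1000, 0, 140)
  expect_setequal(unique(channel_state(y)$symbols), c(0L, 1L))
})

test_that("symbol_series validates its invariants", {
  expect_error(symbol_series(c(0, 4), bits = 2), class = "anticipatr_parameter_error")
  expect_error(symbol_series(integer(0), bits = 1),
               class = "anticipatr_insufficient_data_error")
  expect_error(symbol_series(0:1, bits = 1, time_step_s = 0),
               class = "anticipatr_parameter_error")
})
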
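test_that("generation is bit-identical under a fixed seed and stays in bounds", {
  p <- fish_pair_params(mode = "following", duration = 60, seed = 1)
  a <- generate_pair(p)
  b <- generate_pair(p)
  expect_identical(a$pair$x0, b$pair$x0)
  expect_identical(a$pair$y1, b$pair$y1)
  expect_identical(a$truth$door_events, b$truth$door_events)
  for (g in list(a$pair)) {
    expect_true(all(g$x0 >= 0 & g$x0 <= g$x_span_mm))
    expect_true(all(g$x1 >= 0 & g$x1 <= g$x_span_mm))
  }
})

test_that("door events match channel-state transitions and happen at the door", {
  for (seed in 1:3) {
    g <- generate_pair(fish_pair_params(mode = "following", seed = seed))
    pair <- g$pair
    ev <- g$truth$door_events
    trans0 <- sum(diff(channel_state(pair$y0)$symbols) != 0)
    trans1 <- sum(diff(channel_state(pair$y1)$symbols) != 0)
    expect_equal(nrow(ev), trans0 + trans1)
    expect_equal(sum(door_passage_counts(g$truth, length(pair$door_x_mm))),
                 nrow(ev))
    # transitions only while the agent is within the door region
    # (positions carry ~1 mm of measurement noise)
    for (r in seq_len(nrow(ev))) {
      i <- round(ev$time_s[r] / pair$time_step_s) + 1
      x <- if (ev$agent[r] == 0) pair$x0[i] else pair$x1[i]
      expect_lt(abs(x - pair$door_x_mm[ev$door[r]]), 30 + 6)
    }
  }
})

test_that("the ground-truth leader changes channel first", {
  for (seed in 1:4) {
    g <- generate_pair(fish_pair_params(mode = "following", seed = seed))
    ev <- g$truth$door_events
    expect_gte(nrow(ev), 4)
    # every follower passage must be preceded most recently by a leader passage
    follower_rows <- which(ev$agent == 1)
    preceded <- vapply(follower_rows, function(r) {
      r > 1 && ev$agent[r - 1] == 0
    }, logical(1))
    expect_gte(mean(preceded), 0.95)
    expect_equal(g$truth$leader_label, g$pair$labels[1])
  }
})

test_that("following-mode output sits in the observed statistical envelope", {
  for (seed in 1:5) {
    g <- generate_pair(fish_pair_params(mode = "following", seed = seed))
    rep <- analyze_pair(g$pair)
    expect_gt(rep$x_auto_decay_s[1], 0.3)
    expect_lt(rep$x_auto_decay_s[1], 1.5)
    expect_lt(rep$x_cross$peak_lag_s, 0)          # leader (agent 0) leads
    expect_gte(rep$x_cross$normalized_height, 0.10)
    expect_gte(rep$y_cross$peak_lag_s, -12)
    expect_lte(rep$y_cross$peak_lag_s, -0.3)
    expect_gt(rep$y_auto_decay_s[1], 2.5)
    expect_lt(rep$y_auto_decay_s[1], 20)
  }
})

test_that("independent mode is a near-flat control, like a blocked door", {
  for (seed in 1:2) {
    g <- generate_pair(fish_pair_params(mode = "independent", seed = seed))
    rep <- suppressWarnings(analyze_pair(g$pair))
    expect_lt(rep$x_cross$normalized_height, 0.05)
    expect_null(rep$y_cross)      # each agent stays in its own channel
    expect_true(is.na(g$truth$leader_label))
    expect_equal(nrow(g$truth$door_events), 0)
  }
})

test_that("anticipatory mode produces the positive-x, negative-y signature", {
  for (seed in 1:2) {
    g <- generate_pair(fish_pair_params(mode = "anticipatory", seed = seed))
    rep <- analyze_pair(g$pair)
    expect_gt(rep$x_cross$peak_lag_s, 0)    # follower leads along the channel
    expect_lt(rep$y_cross$peak_lag_s, 0)    # but still trails through the door
    expect_gte(rep$x_cross$normalized_height, 0.10)
  }
})

test_that("door bookkeeping helpers handle edge cases", {
  truth <- structure(
    list(leader_label = "fish0", mode = "following",
         door_events = data.frame(time_s = c(1, 2, 3), agent = 0L,
                                  door = 1L, direction = "down")),
    class = "ground_truth")
  expect_equal(door_passage_counts(truth, 3), c(3, 0, 0))
  truth$door_events <- truth$door_events[0, ]
  expect_equal(door_passage_counts(truth, 3), c(0, 0, 0))
  expect_error(fish_pair_params(door_x_mm = numeric(0)),
               class = "anticipatr_geometry_error")
  expect_error(fish_pair_params(door_x_mm = 300),
               class = "anticipatr_geometry_error")
})
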
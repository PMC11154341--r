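#' Paired trajectories of two agents in a two-channel tank
#'
#' Container for the synchronized tracks of two agents swimming in a
#' rectangular two-channel tank whose channels (each 216 mm long by default)
#' are separated by a wall with one or more doors. The along-channel
#' coordinate is `x` (mm) and the across-channel coordinate is `y` (mm); the
#' wall sits at `wall_y_mm` so `y` encodes which channel an agent occupies.
#'
#' Out-of-range `x` values (tracker jitter beyond the physical span) are
#' clamped to the span edges; the number of clamped samples is kept in the
#' `n_clamped` field and reported via a message.
#'
#' @param x0,y0,x1,y1 Numeric coordinate series (mm), one pair per agent,
#'   all of equal length.
#' @param time_step_s Seconds per sample (default 1/30, i.e. 30 fps).
#' @param x_span_mm Channel length in mm (default 216).
#' @param wall_y_mm Position of the dividing wall along y, mm (default 70).
#' @param door_x_mm Door center positions along x, mm; all within
#'   `[0, x_span_mm]`.
#' @param labels Two agent identifiers.
#'
#' @return An object of class `trajectory_pair`.
#' @examples
#' tp <- trajectory_pair(x0 = c(0, 10, 20), y0 = c(100, 100, 100),
#'                       x1 = c(5, 15, 25), y1 = c(40, 40, 40))
#' tp$n_samples
#' @export
trajectory_pair <- function(x0, y0, x1, y1, time_step_s = 1 / 30,
                            x_span_mm = 216, wall_y_mm = 70, door_x_mm = 108,
                            labels = c("fish0", "fish1")) {
  if (!is_number(time_step_s) || time_step_s <= 0) {
    ad_error("`time_step_s` must be positive", "anticipatr_parameter_error")
  }
  if (!is_number(x_span_mm) || x_span_mm <= 0) {
    ad_error("`x_span_mm` must be positive", "anticipatr_parameter_error")
  }
  n <- length(x0)
  if (length(y0) != n || length(x1) != n || length(y1) != n) {
    ad_error("all four coordinate series must have the same length",
             "anticipatr_format_error")
  }
  if (n < 2L) {
    ad_error("a trajectory pair needs at least 2 samples",
             "anticipatr_insufficient_data_error")
  }
  if (any(door_x_mm < 0 | door_x_mm > x_span_mm)) {
    ad_error("`door_x_mm` must lie within [0, x_span_mm]", "anticipatr_geometry_error")
  }
  clamp <- function(x) pmin(pmax(x, 0), x_span_mm)
  n_clamped <- sum(x0 < 0 | x0 > x_span_mm) + sum(x1 < 0 | x1 > x_span_mm)
  if (n_clamped > 0) {
    message(sprintf("trajectory_pair: clamped %d out-of-span x samples", n_clamped))
  }
  structure(
    list(
      time_step_s = time_step_s, n_samples = n,
      x0 = clamp(as.numeric(x0)), y0 = as.numeric(y0),
      x1 = clamp(as.numeric(x1)), y1 = as.numeric(y1),
      x_span_mm = x_span_mm, wall_y_mm = wall_y_mm,
      door_x_mm = as.numeric(door_x_mm), labels = as.character(labels),
      n_clamped = n_clamped
    ),
    class = "trajectory_pair"
  )
}

#' @export
print.trajectory_pair <- function(x, ...) {
  cat(sprintf(
    "<trajectory_pair> %s vs %s: %d samples @ %.4g s (%.1f s), span %g mm, %d door(s)\n",
    x$labels[1], x$labels[2], x$n_samples, x$time_step_s,
    x$n_samples * x$time_step_s, x$x_span_mm, length(x$door_x_mm)
  ))
  invisible(x)
}

#' Read a trajectory pair from CSV
#'
#' Expects a comma-separated file with header columns `t` (seconds), `x0`,
#' `y0`, `x1`, `y1` (mm). The time column must be strictly increasing and
#' uniformly spaced to within 1% of the median step; the sampling interval is
#' inferred from the median difference.
#'
#' @param path Path to the CSV file.
#' @param x_span_mm,wall_y_mm,door_x_mm,labels Tank geometry, as in
#'   [trajectory_pair()].
#' @return A [trajectory_pair()].
#' @export
read_trajectory_pair <- function(path, x_span_mm = 216, wall_y_mm = 70,
                                 door_x_mm = 108, labels = c("fish0", "fish1")) {
  df <- utils::read.csv(path, check.names = FALSE)
  needed <- c("t", "x0", "y0", "x1", "y1")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    ad_error(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
             "anticipatr_format_error")
  }
  if (nrow(df) < 2L) {
    ad_error("need at least 2 rows", "anticipatr_insufficient_data_error")
  }
  dt <- diff(df$t)
  if (any(dt <= 0)) {
    ad_error("`t` must be strictly increasing", "anticipatr_timing_error")
  }
  med <- stats::median(dt)
  if (any(abs(dt - med) > 0.01 * med)) {
    ad_error("`t` is not uniformly spaced (tolerance 1% of median step)",
             "anticipatr_timing_error")
  }
  trajectory_pair(df$x0, df$y0, df$x1, df$y1, time_step_s = med,
                  x_span_mm = x_span_mm, wall_y_mm = wall_y_mm,
                  door_x_mm = door_x_mm, labels = labels)
}

#' Write a trajectory pair to CSV
#'
#' Writes columns `t`, `x0`, `y0`, `x1`, `y1` with full double precision, so
#' that a read/write round trip reproduces the coordinates to better than
#' 1e-9 mm.
#'
#' @param pair A [trajectory_pair()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_pair <- function(pair, path) {
  stopifnot(inherits(pair, "trajectory_pair"))
  if (pair$n_samples < 2L) {
    ad_error("refusing to write a trajectory with fewer than 2 samples",
             "anticipatr_insufficient_data_error")
  }
  df <- data.frame(
    t = (seq_len(pair$n_samples) - 1L) * pair$time_step_s,
    x0 = pair$x0, y0 = pair$y0, x1 = pair$x1, y1 = pair$y1
  )
  old <- options(digits = 17, scipen = 100)
  on.exit(options(old))
  tryCatch(
    suppressWarnings(utils::write.csv(df, path, row.names = FALSE, quote = FALSE)),
    error = function(e) ad_error(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
                                 "anticipatr_io_error")
  )
  invisible(path)
}

#' Discretize along-channel position into 2^bits equal-width states
#'
#' Bins are anchored at the physical tank span `[0, x_span_mm]`, not at the
#' data range, so the state of a position does not depend on where the agent
#' happened to swim. A position exactly at the far wall maps to the last
#' state; positions outside the span (tracker jitter) are clamped to the edge
#' bins.
#'
#' @param x Numeric position series, mm.
#' @param bits Bit depth; the span is divided into `2^bits` states. Capped at
#'   16 to guard against state-space explosion.
#' @param x_span_mm Channel length, mm.
#' @param time_step_s Seconds per sample, attached to the result.
#' @return A [symbol_series()].
#' @examples
#' discretize_x(c(0, 107.9, 216), bits = 2)$symbols  # 0, 1, 3
#' @export
discretize_x <- function(x, bits = 2, x_span_mm = 216, time_step_s = 1 / 30) {
  if (!is_count(bits) || bits < 1) {
    ad_error("`bits` must be a positive integer", "anticipatr_parameter_error")
  }
  if (bits > 16) {
    ad_error("`bits` > 16 would explode the state space", "anticipatr_resolution_error")
  }
  if (!is_number(x_span_mm) || x_span_mm <= 0) {
    ad_error("`x_span_mm` must be positive", "anticipatr_parameter_error")
  }
  k <- 2^bits
  s <- floor(pmin(pmax(x, 0), x_span_mm) / (x_span_mm / k))
  s[s >= k] <- k - 1L
  symbol_series(as.integer(s), bits = bits, time_step_s = time_step_s)
}

#' Channel membership as a 1-bit state series
#'
#' Maps the across-channel coordinate to a binary channel state: state 0 for
#' the upper channel (`y > wall_y_mm`) and state 1 for the lower channel. A
#' position exactly on the divider is assigned to the lower channel; the
#' choice is arbitrary but fixed, and mutual information is invariant to the
#' labeling.
#'
#' @param y Numeric across-channel positions, mm.
#' @param wall_y_mm Divider position, mm.
#' @param time_step_s Seconds per sample, attached to the result.
#' @return A 1-bit [symbol_series()].
#' @examples
#' channel_state(c(80, 10, 70))$symbols  # 0, 1, 1
#' @export
channel_state <- function(y, wall_y_mm = 70, time_step_s = 1 / 30) {
  symbol_series(as.integer(y <= wall_y_mm), bits = 1, time_step_s = time_step_s)
}
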
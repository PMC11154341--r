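#' Parameters of the synthetic two-agent tank trajectory generator
#'
#' The generator emulates the statistical structure of paired recordings in a
#' two-channel tank. Each agent's along-channel position is the sum of a slow
#' intentional component and an independent fast "wiggle" (an
#' Ornstein-Uhlenbeck jitter). The leader's slow component relaxes toward a
#' goal that alternates between the channel ends at a Poisson rate, which
#' reproduces the end-dwelling of real animals; channel changes can only
#' happen near a door. The follower either
#' \itemize{
#'   \item tracks the leader's position with a fixed delay
#'     (`mode = "following"`),
#'   \item applies a negative-group-delay filter to the leader's slow
#'     component (`mode = "anticipatory"`), so its position leads the
#'     leader's in time while its channel changes still trail — the
#'     anticipatory signature, or
#'   \item moves independently in the other channel with the door blocked
#'     (`mode = "independent"`), the no-interaction control.
#' }
#' In anticipatory mode the leader's slow component is a band-limited
#' wandering signal (lowpass-filtered Ornstein-Uhlenbeck process) rather
#' than the goal telegraph: anticipation by a causal filter is only possible
#' for a predictable, band-limited drive, and the unpredictable goal jumps
#' of the telegraph carry no anticipatable structure.
#'
#' @param mode `"following"`, `"anticipatory"` or `"independent"`.
#' @param fps Sampling rate, Hz.
#' @param duration Recording length, s.
#' @param l_mm Channel length, mm.
#' @param wall_y_mm Divider position, mm.
#' @param door_x_mm Door center position(s) along x, mm (one or three).
#' @param door_radius_mm Half-width of the door region within which channel
#'   changes are possible, mm.
#' @param leader_relax_s Leader's relaxation time toward its goal, s.
#' @param goal_switch_rate_hz Poisson rate of end-to-end goal switching, Hz.
#' @param door_cross_prob_per_s Leader's passage hazard while within the door
#'   region, 1/s. `NULL` picks a mode-dependent default: 0.6 for the
#'   transit-style goal-telegraph leader, 0.1 for the anticipatory-mode
#'   wandering leader, which lingers near the door far longer per excursion,
#'   so a lower decision hazard keeps the channel-change rate and the
#'   channel-state memory time in the observed multi-second range.
#' @param follower_delay_s Target lag of the follower behind the leader, s
#'   (following mode).
#' @param attend_on_rate_hz,attend_off_rate_hz Following mode only: rates of
#'   the follower's attention telegraph. While attending, the follower's
#'   target is the delayed leader position; while away it pursues its own
#'   end-to-end goal. Intermittent attention sets the cross-TLMI peak height
#'   (interaction strength) without touching the peak lag; the defaults give
#'   about two-thirds attention and heights around 0.2-0.4 of the auto peak,
#'   as observed in interacting pairs.
#' @param follower_relax_s Follower's relaxation time toward its target, s.
#' @param follower_cross_hazard_per_s Follower's passage hazard while within
#'   the door region once the leader has changed channel, 1/s.
#' @param pos_noise_mm Additive measurement noise on emitted positions, mm.
#' @param proc_noise_mm Wiggle amplitude, mm per sqrt(s).
#' @param wiggle_tau_s Relaxation time of the wiggle, s.
#' @param margin_mm Offset of the goal points from the channel ends, mm.
#' @param ngd Anticipatory-mode settings: `alpha`, `k` (1/s) and `td` (s) of
#'   the follower's negative-group-delay filter, plus the leader's slow
#'   component (`leader_ou_tau_s`, `leader_lowpass_hz`,
#'   `leader_lowpass_order`, `leader_sd_mm`).
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return A validated list of class `fish_pair_params`.
#' @export
fish_pair_params <- function(mode = c("following", "anticipatory", "independent"),
                             fps = 30, duration = 500, l_mm = 216,
                             wall_y_mm = 70, door_x_mm = 108,
                             door_radius_mm = 30,
                             leader_relax_s = 0.5, goal_switch_rate_hz = 0.15,
                             door_cross_prob_per_s = NULL,
                             follower_delay_s = 0.5, follower_relax_s = 0.3,
                             follower_cross_hazard_per_s = 2,
                             attend_on_rate_hz = 0.3, attend_off_rate_hz = 0.15,
                             pos_noise_mm = 1, proc_noise_mm = 25,
                             wiggle_tau_s = 0.3,
                             margin_mm = 20,
                             ngd = list(alpha = 10, k = 8, td = 2,
                                        leader_ou_tau_s = 2,
                                        leader_lowpass_hz = 0.2,
                                        leader_lowpass_order = 4,
                                        leader_sd_mm = 70),
                             seed = NULL) {
  mode <- match.arg(mode)
  for (nm in c("fps", "duration", "l_mm", "leader_relax_s", "follower_relax_s",
               "wiggle_tau_s")) {
    val <- get(nm)
    if (!is_number(val) || val <= 0) {
      ad_error(sprintf("`%s` must be a positive number", nm), "anticipatr_parameter_error")
    }
  }
  if (!is_number(follower_delay_s) || follower_delay_s < 0) {
    ad_error("`follower_delay_s` must be >= 0", "anticipatr_parameter_error")
  }
  if (length(door_x_mm) < 1L) {
    ad_error("at least one door position is required", "anticipatr_geometry_error")
  }
  if (any(door_x_mm < 0 | door_x_mm > l_mm)) {
    ad_error("`door_x_mm` must lie within [0, l_mm]", "anticipatr_geometry_error")
  }
  if (is.null(door_cross_prob_per_s)) {
    door_cross_prob_per_s <- if (mode == "anticipatory") 0.1 else 0.6
  }
  structure(
    list(mode = mode, fps = fps, duration = duration, l_mm = l_mm,
         wall_y_mm = wall_y_mm, door_x_mm = as.numeric(door_x_mm),
         door_radius_mm = door_radius_mm,
         leader_relax_s = leader_relax_s,
         goal_switch_rate_hz = goal_switch_rate_hz,
         door_cross_prob_per_s = door_cross_prob_per_s,
         follower_delay_s = follower_delay_s, follower_relax_s = follower_relax_s,
         follower_cross_hazard_per_s = follower_cross_hazard_per_s,
         attend_on_rate_hz = attend_on_rate_hz,
         attend_off_rate_hz = attend_off_rate_hz,
         pos_noise_mm = pos_noise_mm, proc_noise_mm = proc_noise_mm,
         wiggle_tau_s = wiggle_tau_s, margin_mm = margin_mm,
         ngd = ngd, seed = seed),
    class = "fish_pair_params"
  )
}

# OU jitter: AR(1) recursion driven by pre-drawn standard normals.
ou_series <- function(w, dt, tau, sigma) {
  as.numeric(stats::filter(sigma * sqrt(dt) * w, 1 - dt / tau, method = "recursive"))
}

# Slow goal-seeking component: a goal telegraph through first-order relaxation.
telegraph_slow <- function(n, dt, goals, rate, relax, u_switch, x_start) {
  flips <- cumsum(c(0, (u_switch[-n] < rate * dt)))
  goal_pos <- goals[1 + flips %% 2]
  a <- dt / relax
  x_start + as.numeric(stats::filter(a * (goal_pos - x_start), 1 - a,
                                     method = "recursive"))
}

#' Generate a synthetic trajectory pair with ground truth
#'
#' Runs the stochastic tank model of [fish_pair_params()] and returns both
#' the measured trajectories and the generating truth. The leader is always
#' agent 0 (`labels[1]`); in independent mode there is no leader and the
#' agents are confined to separate channels, the door-blocked control
#' condition.
#'
#' @param params A [fish_pair_params()] object.
#' @return A list with components `pair` (a [trajectory_pair()]) and `truth`
#'   (class `ground_truth`: `leader_label`, `mode` and `door_events`, a
#'   data.frame of `time_s`, `agent`, `door`, `direction`).
#' @export
generate_pair <- function(params = fish_pair_params()) {
  stopifnot(inherits(params, "fish_pair_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  p <- params
  dt <- 1 / p$fps
  n <- round(p$duration * p$fps)
  doors <- p$door_x_mm
  center <- p$l_mm / 2
  goals <- c(p$margin_mm, p$l_mm - p$margin_mm)
  independent <- p$mode == "independent"

  # randomness in fixed order for reproducibility
  u_goal0 <- stats::runif(n); u_goal1 <- stats::runif(n)
  u_cross0 <- stats::runif(n); u_cross1 <- stats::runif(n)
  u_att <- stats::runif(n)
  w_slow <- stats::rnorm(n)
  wig0 <- ou_series(stats::rnorm(n), dt, p$wiggle_tau_s, p$proc_noise_mm)
  wig1 <- ou_series(stats::rnorm(n), dt, p$wiggle_tau_s, p$proc_noise_mm)

  if (p$mode == "anticipatory") {
    ng <- p$ngd
    ou <- ou_series(w_slow, dt, ng$leader_ou_tau_s, 1)
    band <- butter_lowpass(ou, ng$leader_lowpass_hz, dt, ng$leader_lowpass_order)
    slow0 <- center + band / stats::sd(band) * ng$leader_sd_mm
  } else {
    slow0 <- telegraph_slow(n, dt, goals, p$goal_switch_rate_hz,
                            p$leader_relax_s, u_goal0, center)
  }
  x0 <- pmin(pmax(slow0 + wig0, 0), p$l_mm)

  x1 <- switch(
    p$mode,
    following = {
      d <- max(1L, round(p$follower_delay_s * p$fps))
      tgt_leader <- c(rep(x0[1], d), x0[1:(n - d)])
      # intermittent attention: a two-state Markov telegraph
      att <- logical(n)
      att[1] <- TRUE
      for (i in seq_len(n - 1L)) {
        att[i + 1L] <- if (att[i]) u_att[i] > p$attend_off_rate_hz * dt
                       else u_att[i] < p$attend_on_rate_hz * dt
      }
      flips1 <- cumsum(c(0, (u_goal1[-n] < p$goal_switch_rate_hz * dt)))
      own_goal <- goals[1 + flips1 %% 2]
      tgt <- ifelse(att, tgt_leader, own_goal)
      a <- dt / p$follower_relax_s
      slow1 <- x0[1] + as.numeric(stats::filter(a * (tgt - x0[1]), 1 - a,
                                                method = "recursive"))
      pmin(pmax(slow1 + wig1, 0), p$l_mm)
    },
    anticipatory = {
      ng <- p$ngd
      np <- ngd_params(alpha = ng$alpha, k = ng$k,
                       td = round(ng$td / dt) * dt, dt = dt, duration = n * dt)
      z <- simulate_ngd(slow0 - center, np)
      pmin(pmax(center + z * (ng$alpha + ng$k) / ng$k + wig1, 0), p$l_mm)
    },
    independent = {
      slow1 <- telegraph_slow(n, dt, goals, p$goal_switch_rate_hz,
                              p$leader_relax_s, u_goal1, center)
      pmin(pmax(slow1 + wig1, 0), p$l_mm)
    }
  )

  # channel membership: changes only inside a door region
  nearest0 <- vapply(x0, function(x) which.min(abs(doors - x)), integer(1))
  near0 <- abs(doors[nearest0] - x0) <= p$door_radius_mm
  events <- list()
  if (independent) {
    c0 <- rep(0L, n)
    c1 <- rep(1L, n)
  } else {
    ev0 <- near0 & (u_cross0 < p$door_cross_prob_per_s * dt)
    c0 <- as.integer(cumsum(c(0, utils::head(ev0, -1))) %% 2)
    for (i in which(ev0[-n])) {
      events[[length(events) + 1L]] <- data.frame(
        time_s = (i - 1) * dt, agent = 0L, door = nearest0[i],
        direction = if (c0[i] == 0L) "down" else "up")
    }
    nearest1 <- vapply(x1, function(x) which.min(abs(doors - x)), integer(1))
    near1 <- abs(doors[nearest1] - x1) <= p$door_radius_mm
    c1 <- integer(n)
    for (i in seq_len(n - 1L)) {
      c1[i + 1L] <- c1[i]
      if (c1[i] != c0[i + 1L] && near1[i] &&
          u_cross1[i] < p$follower_cross_hazard_per_s * dt) {
        events[[length(events) + 1L]] <- data.frame(
          time_s = (i - 1) * dt, agent = 1L, door = nearest1[i],
          direction = if (c1[i] == 0L) "down" else "up")
        c1[i + 1L] <- 1L - c1[i]
      }
    }
  }

  # across-channel coordinate: channel baseline plus bounded jitter
  base_y <- function(ch) ifelse(ch == 0L, p$wall_y_mm + 35, p$wall_y_mm - 35)
  jit <- function() pmin(pmax(ou_series(stats::rnorm(n), dt, 1, 8), -30), 30)
  y0 <- base_y(c0) + jit()
  y1 <- base_y(c1) + jit()

  mx <- function(x) pmin(pmax(x + p$pos_noise_mm * stats::rnorm(n), 0), p$l_mm)
  pair <- trajectory_pair(
    x0 = mx(x0), y0 = y0, x1 = mx(x1), y1 = y1,
    time_step_s = dt, x_span_mm = p$l_mm, wall_y_mm = p$wall_y_mm,
    door_x_mm = doors
  )
  door_events <- if (length(events)) {
    ev <- do.call(rbind, events)
    ev <- ev[order(ev$time_s), , drop = FALSE]
    rownames(ev) <- NULL
    ev
  } else {
    data.frame(time_s = numeric(0), agent = integer(0), door = integer(0),
               direction = character(0))
  }
  truth <- structure(
    list(leader_label = if (independent) NA_character_ else pair$labels[1],
         mode = p$mode, door_events = door_events),
    class = "ground_truth"
  )
  list(pair = pair, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> mode %s, leader %s, %d door passage(s)\n",
              x$mode, x$leader_label, nrow(x$door_events)))
  invisible(x)
}

#' Count door passages per door
#'
#' Pools the door-passage events of both agents into per-door counts.
#'
#' @param truth A `ground_truth` object from [generate_pair()].
#' @param n_doors Number of doors in the tank.
#' @return Integer vector of length `n_doors`.
#' @export
door_passage_counts <- function(truth, n_doors) {
  stopifnot(inherits(truth, "ground_truth"), is_count(n_doors), n_doors >= 1)
  tabulate(truth$door_events$door, nbins = n_doors)
}
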
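#' Analysis configuration for the pair pipeline
#'
#' Collects the tunable parameters of [analyze_pair()]: the along-channel
#' discretization depth (2 bits by default; 4 bits gives similar but noisier
#' results), the TLMI lag windows for the fast along-channel dynamics and the
#' slow channel-choice dynamics, the Granger order search, the transfer
#' entropy history lengths, and the classification thresholds.
#'
#' @param bits_x Bit depth for the along-channel discretization.
#' @param max_lag_x_s TLMI lag window half-width for x curves, s.
#' @param max_lag_y_s TLMI lag window half-width for channel-state curves, s.
#' @param p_max Largest Granger autoregression order considered.
#' @param gc_order Fixed Granger order; `NULL` selects by `criterion`.
#' @param criterion Order-selection criterion, `"BIC"` or `"AIC"`.
#' @param te_h Transfer-entropy history lengths, steps. The default 2..5
#'   balances temporal reach against the exponential growth of the joint
#'   state space, which biases the plug-in estimate at long histories.
#' @param min_norm_height Interaction threshold on the normalized cross-TLMI
#'   peak height; pairs below it are called `no_interaction`.
#' @param zero_tol_s Lags within this tolerance of zero are considered
#'   unresolved (`NULL`: two frames). The sign rule that separates
#'   anticipatory from following pairs is meaningless without a resolvable
#'   lead.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(bits_x = 2, max_lag_x_s = 5, max_lag_y_s = 30,
                            p_max = 20, gc_order = NULL,
                            criterion = c("BIC", "AIC"), te_h = 2:5,
                            min_norm_height = 0.10, zero_tol_s = NULL) {
  structure(
    list(bits_x = bits_x, max_lag_x_s = max_lag_x_s, max_lag_y_s = max_lag_y_s,
         p_max = p_max, gc_order = gc_order, criterion = match.arg(criterion),
         te_h = te_h, min_norm_height = min_norm_height, zero_tol_s = zero_tol_s),
    class = "analysis_config"
  )
}

flip_curve <- function(curve) {
  o <- order(-curve$lag_steps)
  curve$lag_steps <- -curve$lag_steps[o]
  curve$lag_s <- -curve$lag_s[o]
  curve$values_bits <- curve$values_bits[o]
  curve
}

#' Analyze a trajectory pair end to end
#'
#' Discretizes the along-channel positions to `bits_x` resolution and the
#' across-channel positions to channel states, computes the auto and cross
#' time-lag mutual information curves and their summaries for both
#' components, relabels the agents so that the channel-state cross peak lag
#' is nonpositive (making agent 0 the information source, the agent whose
#' channel changes come first), and then runs the three directed
#' information-flow detectors: Granger causality at the selected order on
#' the raw positions, Liang's T on the raw positions, and transfer entropy
#' on the discretized positions at each configured history length.
#'
#' If one agent never changes channel, the channel-state analysis is skipped
#' with a warning (a constant series carries no information) and no
#' relabeling occurs.
#'
#' @param pair A [trajectory_pair()].
#' @param config An [analysis_config()].
#' @return An object of class `pair_report`: `x_cross` and `y_cross`
#'   ([peak_summary()]s; `y_cross` may be `NULL`), `x_auto_decay_s` and
#'   `y_auto_decay_s` (per agent, after relabeling), `gc`, `liang`, `te`
#'   (list over history lengths), `relabeled`, `labels`, plus the lag curves
#'   under `curves`.
#' @export
analyze_pair <- function(pair, config = analysis_config()) {
  stopifnot(inherits(pair, "trajectory_pair"))
  cfg <- config
  dt <- pair$time_step_s
  if (pair$n_samples * dt < 30) {
    ad_error("need at least 30 s of samples", "anticipatr_insufficient_data_error")
  }

  sy0 <- channel_state(pair$y0, pair$wall_y_mm, dt)
  sy1 <- channel_state(pair$y1, pair$wall_y_mm, dt)
  y_ok <- length(unique(sy0$symbols)) > 1L && length(unique(sy1$symbols)) > 1L
  relabeled <- FALSE
  if (y_ok) {
    y_cross <- tlmi_curve(sy0, sy1, cfg$max_lag_y_s, kind = "cross")
    if (y_cross$lag_s[curve_peak(y_cross)] > 0) {
      # convention: the channel-state cross peak is nonpositive, so agent 0
      # is the one that changes channel first (the information source)
      relabeled <- TRUE
      pair[c("x0", "y0", "x1", "y1")] <- pair[c("x1", "y1", "x0", "y0")]
      pair$labels <- rev(pair$labels)
      tmp <- sy0; sy0 <- sy1; sy1 <- tmp
      y_cross <- flip_curve(y_cross)
    }
    y_auto0 <- tlmi_curve(sy0, sy0, cfg$max_lag_y_s, kind = "auto")
    y_auto1 <- tlmi_curve(sy1, sy1, cfg$max_lag_y_s, kind = "auto")
    y_sum <- peak_summary(y_cross, y_auto0, y_auto1)
    y_decay <- c(suppressWarnings(half_decay_time(y_auto0)),
                 suppressWarnings(half_decay_time(y_auto1)))
  } else {
    warning("an agent never changes channel; channel-state analysis skipped")
    y_cross <- y_auto0 <- y_auto1 <- NULL
    y_sum <- NULL
    y_decay <- c(NA_real_, NA_real_)
  }

  sx0 <- discretize_x(pair$x0, cfg$bits_x, pair$x_span_mm, dt)
  sx1 <- discretize_x(pair$x1, cfg$bits_x, pair$x_span_mm, dt)
  x_cross <- tlmi_curve(sx0, sx1, cfg$max_lag_x_s, kind = "cross")
  x_auto0 <- tlmi_curve(sx0, sx0, cfg$max_lag_x_s, kind = "auto")
  x_auto1 <- tlmi_curve(sx1, sx1, cfg$max_lag_x_s, kind = "auto")
  x_sum <- peak_summary(x_cross, x_auto0, x_auto1)
  x_decay <- c(suppressWarnings(half_decay_time(x_auto0)),
               suppressWarnings(half_decay_time(x_auto1)))

  order_p <- if (!is.null(cfg$gc_order)) cfg$gc_order else
    select_var_order(pair$x0, pair$x1, cfg$p_max, cfg$criterion)$order
  gc <- granger_f(pair$x0, pair$x1, order_p)
  liang <- liang_t(pair$x0, pair$x1, dt)
  te <- lapply(sort(cfg$te_h), function(h) {
    suppressWarnings(transfer_entropy(sx0, sx1, h))
  })

  structure(
    list(x_cross = x_sum, y_cross = y_sum,
         x_auto_decay_s = x_decay, y_auto_decay_s = y_decay,
         gc = gc, liang = liang, te = te,
         relabeled = relabeled, labels = pair$labels,
         time_step_s = dt,
         curves = list(x_cross = x_cross, x_auto0 = x_auto0, x_auto1 = x_auto1,
                       y_cross = y_cross, y_auto0 = y_auto0, y_auto1 = y_auto1),
         config = cfg),
    class = "pair_report"
  )
}

#' @export
print.pair_report <- function(x, ...) {
  cat(sprintf("<pair_report> %s (source) vs %s%s\n", x$labels[1], x$labels[2],
              if (x$relabeled) " [relabeled]" else ""))
  cat(sprintf("  x cross: peak %+.3g s, height %.3g of auto; auto half-decay %.3g / %.3g s\n",
              x$x_cross$peak_lag_s, x$x_cross$normalized_height,
              x$x_auto_decay_s[1], x$x_auto_decay_s[2]))
  if (!is.null(x$y_cross)) {
    cat(sprintf("  y cross: peak %+.3g s, height %.3g of auto; auto half-decay %.3g / %.3g s\n",
                x$y_cross$peak_lag_s, x$y_cross$normalized_height,
                x$y_auto_decay_s[1], x$y_auto_decay_s[2]))
  } else {
    cat("  y cross: skipped (single-channel recording)\n")
  }
  cat(sprintf("  GC order %d: F fwd %.3g (p %.3g), F rev %.3g (p %.3g); Liang T %.3g / %.3g\n",
              x$gc$order, x$gc$f_fwd, x$gc$p_fwd, x$gc$f_rev, x$gc$p_rev,
              x$liang$t_fwd, x$liang$t_rev))
  invisible(x)
}

#' Classify a pair as following, anticipatory, no-interaction or ambiguous
#'
#' Applies the sign rule to a [analyze_pair()] report, after its agent-0-
#' leads-in-y relabeling: a pair whose normalized along-channel cross peak is
#' below `min_norm_height` shows no interaction; a resolvable positive
#' along-channel peak lag (the channel-choice follower leading in position)
#' is the anticipatory signature; a resolvable negative lag is plain
#' following; a lag within `zero_tol_s` of zero is ambiguous, since the sign
#' rule cannot operate without a significant lead. A report without
#' channel-state information (single-channel recording) can only be called
#' `no_interaction` or `ambiguous`.
#'
#' @param report A `pair_report`.
#' @param min_norm_height Interaction threshold on the normalized x cross
#'   peak height.
#' @param zero_tol_s Zero-lag tolerance in seconds (`NULL`: two frames).
#' @return An object of class `ad_call` with fields `label` and `evidence`.
#' @export
classify_ad <- function(report, min_norm_height = 0.10, zero_tol_s = NULL) {
  stopifnot(inherits(report, "pair_report"))
  if (is.null(zero_tol_s)) zero_tol_s <- 2 * report$time_step_s
  x_lag <- report$x_cross$peak_lag_s
  height <- report$x_cross$normalized_height
  y_lag <- if (!is.null(report$y_cross)) report$y_cross$peak_lag_s else NA_real_
  label <-
    if (height < min_norm_height) "no_interaction"
    else if (is.na(y_lag) || abs(x_lag) <= zero_tol_s) "ambiguous"
    else if (x_lag > 0) "anticipatory"
    else "following"
  structure(
    list(label = label,
         evidence = list(x_peak_lag_s = x_lag, y_peak_lag_s = y_lag,
                         normalized_height = height,
                         min_norm_height = min_norm_height,
                         zero_tol_s = zero_tol_s)),
    class = "ad_call"
  )
}

#' @export
print.ad_call <- function(x, ...) {
  cat(sprintf("<ad_call> %s (x peak %+.3g s, y peak %+.3g s, height %.3g)\n",
              x$label, x$evidence$x_peak_lag_s, x$evidence$y_peak_lag_s,
              x$evidence$normalized_height))
  invisible(x)
}

#' Pool door-passage counts into door-choice probabilities
#'
#' Pools counts over experiments and reports the per-door percentage of all
#' passages, rounded to 0.1.
#'
#' @param counts A vector of per-door counts, or a matrix/data.frame with one
#'   row per experiment and one column per door.
#' @return Numeric vector of percentages (one per door), summing to ~100.
#' @examples
#' door_choice_probabilities(rbind(c(28, 19, 33), c(28, 20, 20),
#'                                 c(51, 16, 31), c(20, 6, 18)))
#' @export
door_choice_probabilities <- function(counts) {
  m <- if (is.null(dim(counts))) matrix(counts, nrow = 1) else as.matrix(counts)
  totals <- colSums(m)
  grand <- sum(totals)
  if (grand <= 0) {
    ad_error("no passages at all: probabilities undefined",
             "anticipatr_undefined_probability_error")
  }
  round(100 * totals / grand, 1)
}

report_row_tlmi <- function(i, report, call) {
  data.frame(
    expt = i, label0 = report$labels[1], label1 = report$labels[2],
    x_peak_pos_s = report$x_cross$peak_lag_s,
    x_peak_height = report$x_cross$normalized_height,
    x_decay_s = report$x_auto_decay_s[1],
    y_peak_pos_s = if (!is.null(report$y_cross)) report$y_cross$peak_lag_s else NA_real_,
    y_peak_height = if (!is.null(report$y_cross)) report$y_cross$normalized_height else NA_real_,
    y_decay_s = report$y_auto_decay_s[1],
    relabeled = report$relabeled, call = call$label
  )
}

report_row_dif <- function(i, report) {
  data.frame(
    expt = i, order = report$gc$order,
    f_0to1 = report$gc$f_fwd, f_1to0 = report$gc$f_rev,
    p_0to1 = report$gc$p_fwd, p_1to0 = report$gc$p_rev,
    t_0to1 = report$liang$t_fwd, t_1to0 = report$liang$t_rev
  )
}

report_to_list <- function(report, call) {
  list(
    labels = report$labels, relabeled = report$relabeled,
    x_cross = unclass(report$x_cross), y_cross = unclass(report$y_cross),
    x_auto_decay_s = report$x_auto_decay_s, y_auto_decay_s = report$y_auto_decay_s,
    gc = unclass(report$gc), liang = unclass(report$liang),
    te = lapply(report$te, unclass),
    call = list(label = call$label, evidence = call$evidence)
  )
}

#' Batch analysis of trajectory files or generator settings
#'
#' Runs [analyze_pair()] and [classify_ad()] on each input — a path to a
#' trajectory CSV or a [fish_pair_params()] object — writing one JSON report
#' per pair plus two CSV summary tables (TLMI peak/decay summaries, and
#' Granger/Liang statistics) and a JSON run log into `out_dir`. Inputs that
#' fail are logged and skipped; the batch continues.
#'
#' @param inputs A list of file paths and/or [fish_pair_params()] objects.
#' @param config An [analysis_config()].
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, a list with the two summary data.frames (`tlmi`, `dif`)
#'   and the per-input `failures`.
#' @export
run_batch <- function(inputs, config = analysis_config(), out_dir) {
  if (length(inputs) < 1L) ad_error("no inputs", "anticipatr_input_error")
  if (!is.list(inputs) || inherits(inputs, "fish_pair_params")) inputs <- list(inputs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tlmi_rows <- list(); dif_rows <- list(); failures <- list()
  for (i in seq_along(inputs)) {
    res <- tryCatch({
      inp <- inputs[[i]]
      pair <- if (inherits(inp, "fish_pair_params")) generate_pair(inp)$pair
              else read_trajectory_pair(inp)
      report <- suppressWarnings(analyze_pair(pair, config))
      call <- classify_ad(report, config$min_norm_height,
                          config$zero_tol_s %||% (2 * report$time_step_s))
      jsonlite::write_json(
        report_to_list(report, call),
        file.path(out_dir, sprintf("pair_%03d.json", i)),
        auto_unbox = TRUE, digits = NA, null = "null"
      )
      list(tlmi = report_row_tlmi(i, report, call), dif = report_row_dif(i, report))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(input = i, message = conditionMessage(res))
    } else {
      tlmi_rows[[length(tlmi_rows) + 1L]] <- res$tlmi
      dif_rows[[length(dif_rows) + 1L]] <- res$dif
    }
  }
  if (length(tlmi_rows) == 0L) {
    ad_error("all inputs failed", "anticipatr_input_error")
  }
  tlmi_df <- do.call(rbind, tlmi_rows)
  dif_df <- do.call(rbind, dif_rows)
  old <- options(digits = 17, scipen = 100)
  on.exit(options(old))
  utils::write.csv(tlmi_df, file.path(out_dir, "summary_tlmi.csv"), row.names = FALSE)
  utils::write.csv(dif_df, file.path(out_dir, "summary_dif.csv"), row.names = FALSE)
  seeds <- vapply(inputs, function(x)
    if (inherits(x, "fish_pair_params") && !is.null(x$seed)) x$seed else NA_real_,
    numeric(1))
  jsonlite::write_json(
    list(n_inputs = length(inputs), n_ok = nrow(tlmi_df),
         failures = failures, seeds = seeds,
         config = unclass(config),
         package_version = as.character(utils::packageVersion("anticipatr")),
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, null = "null"
  )
  invisible(list(tlmi = tlmi_df, dif = dif_df, failures = failures))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
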
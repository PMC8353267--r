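#' Acquisition scheduling configuration
#'
#' Parameters of the time-scheduled SRM method: the retention-time window
#' placed around each peptide's predicted elution, the per-transition
#' dwell time, the maximum acceptable cycle time, any per-transition
#' interscan overhead and the gradient length. Defaults follow a
#' 30-min-gradient multiplexed method with a 4-min window, 10-ms dwell and
#' a 1.7-s cycle-time budget; the 170 x 10 ms = 1.7 s arithmetic implies
#' negligible interscan overhead, hence the 0 default.
#'
#' @param window_width RT window width in minutes.
#' @param dwell_time Per-transition dwell time in seconds.
#' @param max_cycle_time Maximum cycle time in seconds.
#' @param interscan_overhead Per-transition overhead in seconds.
#' @param gradient_length Gradient length in minutes.
#' @return A `schedule_config` list.
#' @export
schedule_config <- function(window_width = 4, dwell_time = 0.010,
                            max_cycle_time = 1.7, interscan_overhead = 0,
                            gradient_length = 30) {
  stopifnot(window_width > 0, dwell_time > 0, max_cycle_time > 0,
            interscan_overhead >= 0, gradient_length > 0,
            window_width <= gradient_length)
  structure(list(window_width = window_width, dwell_time = dwell_time,
                 max_cycle_time = max_cycle_time,
                 interscan_overhead = interscan_overhead,
                 gradient_length = gradient_length),
            class = "schedule_config")
}

#' Fit the iRT-to-RT calibration line
#'
#' Ordinary least squares of observed retention time (min) on the
#' dimensionless iRT score, as used to schedule acquisition from annotated
#' iRT reference peptides.
#'
#' @param points Data frame with columns `irt` and `rt` (observed, min).
#' @return An `rt_calibration`: slope (min per iRT unit), intercept (min),
#'   residual_sd (min), n_points.
#' @export
fit_rt_calibration <- function(points) {
  if (!all(c("irt", "rt") %in% names(points))) {
    stop("calibration points need columns 'irt' and 'rt'", call. = FALSE)
  }
  if (nrow(points) < 2 || length(unique(points$irt)) < 2) {
    stop("need at least 2 points with distinct iRT", call. = FALSE)
  }
  fit <- stats::lm(rt ~ irt, data = points)
  rsd <- if (nrow(points) > 2) sqrt(sum(stats::residuals(fit)^2) /
                                      (nrow(points) - 2)) else 0
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_sd = rsd, n_points = nrow(points)),
            class = "rt_calibration")
}

#' Predict retention time from iRT
#' @param cal An `rt_calibration`.
#' @param irt iRT score(s).
#' @return Predicted RT in minutes.
#' @export
predict_rt <- function(cal, irt) cal$intercept + cal$slope * irt

#' Assign scheduled RT windows to a panel
#'
#' Each transition gets a window of width `config$window_width` centred on
#' the peptide's predicted RT and clipped (not shifted) to
#' `[0, gradient_length]`. Light and heavy twins co-elute by construction
#' and therefore share one window.
#'
#' @param panel A `protein_panel` whose peptides all carry an iRT.
#' @param cal An `rt_calibration` from [fit_rt_calibration()].
#' @param config A [schedule_config()].
#' @return A `scheduled_method`: `entries` (transition rows plus
#'   `window_start`, `window_end`), `max_concurrency`,
#'   `effective_cycle_time`, `feasible`, and the config.
#' @export
assign_windows <- function(panel, cal, config = schedule_config()) {
  tr <- if (inherits(panel, "protein_panel")) panel$transitions else panel
  if (anyNA(tr$irt)) {
    bad <- unique(tr$peptide_sequence[is.na(tr$irt)])
    stop("peptides without iRT: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  centre <- predict_rt(cal, tr$irt)
  half <- config$window_width / 2
  entries <- tr
  entries$window_start <- pmax(0, pmin(centre - half,
                                       config$gradient_length))
  entries$window_end <- pmin(config$gradient_length,
                             pmax(centre + half, 0))
  method <- structure(list(entries = entries, max_concurrency = NA_integer_,
                           effective_cycle_time = NA_real_, feasible = NA,
                           config = config),
                      class = "scheduled_method")
  check_feasibility(method, config)
}

#' Maximum number of concurrently scheduled transitions
#'
#' Endpoint sweep over half-open windows `[start, end)`: at each event
#' time, ends are processed before starts, so windows that merely touch do
#' not count as overlapping.
#'
#' @param method A `scheduled_method` (or its `entries` data frame).
#' @return Integer maximum concurrency (0 for an empty method).
#' @export
max_concurrency <- function(method) {
  e <- if (inherits(method, "scheduled_method")) method$entries else method
  if (is.null(e) || !nrow(e)) return(0L)
  ev <- data.frame(t = c(e$window_start, e$window_end),
                   d = c(rep(1L, nrow(e)), rep(-1L, nrow(e))))
  # ends (-1) sort before starts (+1) at equal time: half-open convention
  ev <- ev[order(ev$t, ev$d), ]
  max(0L, cumsum(ev$d))
}

#' Evaluate dwell/cycle-time feasibility of a scheduled method
#'
#' The effective cycle time is the worst-case number of concurrent
#' transitions times the per-transition time (dwell plus interscan
#' overhead); the method is feasible when it does not exceed
#' `max_cycle_time`.
#'
#' @param method A `scheduled_method`.
#' @param config A [schedule_config()].
#' @return The method with `max_concurrency`, `effective_cycle_time` and
#'   `feasible` filled in.
#' @export
check_feasibility <- function(method, config = method$config) {
  k <- max_concurrency(method)
  method$max_concurrency <- k
  method$effective_cycle_time <-
    k * (config$dwell_time + config$interscan_overhead)
  method$feasible <- method$effective_cycle_time <= config$max_cycle_time
  method$config <- config
  method
}

#' @export
print.scheduled_method <- function(x, ...) {
  counts <- transition_counts(x$entries)
  cat(sprintf(paste0("scheduled_method: %d transitions ",
                     "(%d light + %d heavy), max concurrency %d,\n",
                     "  effective cycle time %.2f s (limit %.2f s) — %s\n"),
              counts["total"], counts["light"], counts["heavy"],
              x$max_concurrency, x$effective_cycle_time,
              x$config$max_cycle_time,
              if (isTRUE(x$feasible)) "feasible" else "NOT feasible"))
  invisible(x)
}

#' Export a scheduled method to CSV
#'
#' Transition-list columns plus `window_start` and `window_end` (minutes,
#' 2 decimals).
#'
#' @param method A `scheduled_method`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scheduled_method <- function(method, path) {
  d <- method$entries[, c(.TRANSITION_LIST_COLS, "window_start",
                          "window_end")]
  for (col in c("precursor_mz", "product_mz", "irt")) {
    d[[col]] <- sprintf("%.4f", d[[col]])
  }
  for (col in c("window_start", "window_end")) {
    d[[col]] <- sprintf("%.2f", d[[col]])
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
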
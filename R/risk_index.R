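# Window summaries -> mortality-risk index and alarms. Low RR-interval
# dispersion concentrates projections on few stairs (high concentration),
# accumulation sticks springs (stuck fraction), and failed drainage starves
# the valley (low throughput); each ingredient enters as one bounded term.

#' Risk-index weights
#'
#' The composite index is
#' `risk = a * concentration + b * stuck_fraction + c * (1 - throughput)`,
#' clamped to `[0, 1]`, with `a + b + c = 1`.
#'
#' @param concentration Weight of the entropy-based concentration term.
#' @param stuck Weight of the stuck-time fraction.
#' @param throughput Weight of the drainage-shortfall term.
#' @return Named numeric vector of class `risk_weights`.
#' @export
risk_weights <- function(concentration = 0.4, stuck = 0.4, throughput = 0.2) {
  w <- c(concentration = concentration, stuck = stuck, throughput = throughput)
  if (any(!is.finite(w)) || any(w < 0) || abs(sum(w) - 1) > 1e-8)
    rp_stop("weights must be non-negative and sum to 1", "riskplot_config_error")
  structure(w, class = "risk_weights")
}

#' Alarm thresholds
#'
#' Risk at or above `red` raises a red alarm, at or above `amber` an amber
#' one, otherwise green. The defaults (0.20, 0.25) sit between the index
#' ranges realised by healthy high-variability dynamics (about 0.12-0.18
#' under the default configuration) and near-death low-variability dynamics
#' (about 0.27 and up); see the package vignette for the derivation.
#'
#' @param amber,red Thresholds in `[0, 1]`, `amber < red`.
#' @return Named numeric vector of class `alarm_thresholds`.
#' @export
alarm_thresholds <- function(amber = 0.20, red = 0.25) {
  if (!is_number(amber) || !is_number(red) || amber < 0 || red > 1 ||
      amber >= red)
    rp_stop("need 0 <= amber < red <= 1", "riskplot_config_error")
  structure(c(amber = amber, red = red), class = "alarm_thresholds")
}

.alarm_level <- function(risk, thresholds) {
  ifelse(risk >= thresholds[["red"]], "red",
         ifelse(risk >= thresholds[["amber"]], "amber", "green"))
}

#' Risk index for one window
#'
#' Components, each in `[0, 1]`:
#' * `concentration = 1 - H / log(K)` where `H` is the Shannon entropy of
#'   the window's stair-projection distribution (counts of beats assigned to
#'   each stair, not terminal occupancy, with `0 log 0 = 0`);
#' * `stuck_fraction`: fraction of the window's beats during which at least
#'   one stair was stuck;
#' * `throughput`: `valley / projected`, the share of projected tokens that
#'   reached the valley of life.
#'
#' @param trace An [run_risk_plot()] trace.
#' @param window Window number.
#' @param weights A [risk_weights()] vector.
#' @param thresholds An [alarm_thresholds()] vector.
#' @return A one-row data frame: window id, the three components, `risk`,
#'   `alarm`, and bookkeeping columns (`n_beats`, `projected`, `valley`,
#'   `dropped`, `partial`, `start_time`).
#' @export
window_index <- function(trace, window, weights = risk_weights(),
                         thresholds = alarm_thresholds()) {
  if (!inherits(trace, "rp_trace"))
    rp_stop("`trace` must be an rp_trace", "riskplot_input_error")
  w <- trace$windows[trace$windows$window == window, ]
  if (nrow(w) == 0L)
    rp_stop(sprintf("no window %s in trace", window), "riskplot_input_error")
  if (w$projected == 0L)
    rp_stop(sprintf("window %s is empty; risk undefined", window),
            "riskplot_input_error")
  counts <- trace$counts[w$window, ]
  K <- trace$config$n_stairs
  p <- counts[counts > 0] / sum(counts)
  H <- -sum(p * log(p))
  concentration <- 1 - H / log(K)
  stuck_fraction <- w$stuck_beats / w$n_beats
  throughput <- w$valley / w$projected
  risk <- min(1, max(0, weights[["concentration"]] * concentration +
                       weights[["stuck"]] * stuck_fraction +
                       weights[["throughput"]] * (1 - throughput)))
  data.frame(window = w$window, start_time = w$start_time, n_beats = w$n_beats,
             concentration = concentration, stuck_fraction = stuck_fraction,
             throughput = throughput, risk = risk,
             alarm = .alarm_level(risk, thresholds),
             projected = w$projected, valley = w$valley, dropped = w$dropped,
             partial = w$partial)
}

#' Risk index for every window of a trace
#'
#' @inheritParams window_index
#' @param include_partial Include the trailing incomplete window (flagged
#'   `partial = TRUE`) in the result.
#' @return A data frame with one row per window, ordered by window number.
#' @export
risk_series <- function(trace, weights = risk_weights(),
                        thresholds = alarm_thresholds(),
                        include_partial = TRUE) {
  if (!inherits(trace, "rp_trace"))
    rp_stop("`trace` must be an rp_trace", "riskplot_input_error")
  complete <- trace$windows$window[!trace$windows$partial]
  if (length(complete) == 0L)
    rp_stop(sprintf("no complete window (need %d beats per window, trace has %d processed beats)",
                    trace$config$window_beats,
                    sum(trace$windows$n_beats)), "riskplot_input_error")
  ids <- if (include_partial) trace$windows$window else complete
  out <- do.call(rbind, lapply(ids, window_index, trace = trace,
                               weights = weights, thresholds = thresholds))
  rownames(out) <- NULL
  out
}

#' Per-window SDNN of an RR-interval series
#'
#' Companion dispersion diagnostic to the risk plot: the sample standard
#' deviation of the unflagged intervals in each window. Windows are counted
#' in unflagged beats, matching [run_risk_plot()] windows.
#'
#' @param series An [rri_series].
#' @param window_beats Beats per window.
#' @param mask Optional logical flag vector; flagged intervals are excluded.
#' @return A data frame with `window`, `n` (intervals used), and `sdnn`
#'   (seconds). Windows with fewer than 2 usable intervals get `NA` sdnn.
#' @export
dispersion_summary <- function(series, window_beats = 300L, mask = NULL) {
  if (!inherits(series, "rri_series"))
    rp_stop("`series` must be an rri_series", "riskplot_input_error")
  if (!is_count(window_beats, min = 1L))
    rp_stop("`window_beats` must be an integer >= 1", "riskplot_config_error")
  x <- series$intervals
  if (is.null(mask)) mask <- rep(FALSE, length(x))
  x <- x[!mask]
  if (length(x) < 2L)
    rp_stop("need at least 2 unflagged intervals", "riskplot_input_error")
  win <- (seq_along(x) - 1L) %/% window_beats + 1L
  n <- tapply(x, win, length)
  s <- tapply(x, win, function(v) if (length(v) >= 2L) stats::sd(v) else NA_real_)
  data.frame(window = as.integer(names(n)), n = as.integer(n),
             sdnn = as.numeric(s))
}
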
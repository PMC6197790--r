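# The risk plot (RP): RR intervals are projected as unit tokens onto binned
# "stairs"; a spring under each stair drains up to `drain_rate` tokens per
# beat into the valley-of-life sink; a stair whose occupancy reaches
# `capacity` is stuck and drains nothing for the rest of the window. All
# stair indices are 1-based.

#' Risk-plot configuration
#'
#' @param stair_edges Strictly increasing RR-interval boundaries in seconds
#'   defining `K = length(stair_edges) - 1` stairs. Bins are half-open
#'   `[e_k, e_{k+1})`; the last stair is closed at its right edge. The
#'   default, 120 stairs of 0.01 s over 0.3-1.5 s, resolves dispersion down
#'   to the few-millisecond SDNN scale seen in the near-death regime.
#' @param drain_rate Tokens drained per stair per beat step (integer >= 0).
#' @param capacity Occupancy at or above which a spring fails (integer >= 1,
#'   must exceed `drain_rate`).
#' @param window_beats Beats per analysis window; the state is reset to
#'   empty at each window boundary. 300 beats is about five minutes at
#'   60 bpm, the conventional short-term HRV horizon.
#' @param oor_policy Handling of intervals outside the stair range:
#'   `"clamp"` assigns them to the edge stair, `"drop"` discards them (the
#'   drop is counted, never silent).
#' @return An object of class `rp_config`.
#' @export
rp_config <- function(stair_edges = seq(0.3, 1.5, by = 0.01),
                      drain_rate = 1L, capacity = 8L, window_beats = 300L,
                      oor_policy = c("clamp", "drop")) {
  oor_policy <- match.arg(oor_policy)
  stair_edges <- as.numeric(stair_edges)
  if (length(stair_edges) < 3L || any(diff(stair_edges) <= 0))
    rp_stop("`stair_edges` must be strictly increasing with at least 2 stairs",
            "riskplot_config_error")
  if (!is_count(drain_rate, min = 0L))
    rp_stop("`drain_rate` must be an integer >= 0", "riskplot_config_error")
  if (!is_count(capacity, min = 1L) || capacity <= drain_rate)
    rp_stop("`capacity` must be an integer >= 1 and > drain_rate",
            "riskplot_config_error")
  if (!is_count(window_beats, min = 1L))
    rp_stop("`window_beats` must be an integer >= 1", "riskplot_config_error")
  structure(list(stair_edges = stair_edges,
                 n_stairs = length(stair_edges) - 1L,
                 drain_rate = as.integer(drain_rate),
                 capacity = as.integer(capacity),
                 window_beats = as.integer(window_beats),
                 oor_policy = oor_policy),
            class = "rp_config")
}

#' @export
print.rp_config <- function(x, ...) {
  cat(sprintf(paste0("<rp_config> %d stairs over [%.3g, %.3g] s, drain %d/beat, ",
                     "capacity %d, window %d beats, oor=%s\n"),
              x$n_stairs, x$stair_edges[1], x$stair_edges[length(x$stair_edges)],
              x$drain_rate, x$capacity, x$window_beats, x$oor_policy))
  invisible(x)
}

#' Empty risk-plot state
#'
#' @param config An [rp_config].
#' @return An object of class `rp_state`: per-stair `occupancy`, `stuck`
#'   flags, `valley`, `projected` and `dropped` counters. The conservation
#'   identity `projected == sum(occupancy) + valley + dropped` holds for
#'   every state produced by [project_beat()]/[drain_step()].
#' @export
rp_state <- function(config = rp_config()) {
  structure(list(occupancy = integer(config$n_stairs),
                 stuck = logical(config$n_stairs),
                 valley = 0L, projected = 0L, dropped = 0L),
            class = "rp_state")
}

#' @export
print.rp_state <- function(x, ...) {
  cat(sprintf("<rp_state> projected %d | on stairs %d (%d stuck) | valley %d | dropped %d\n",
              x$projected, sum(x$occupancy), sum(x$stuck), x$valley, x$dropped))
  invisible(x)
}

#' Assign an RR interval to a stair
#'
#' Half-open bins `[e_k, e_{k+1})`, last stair closed at its right edge.
#' Out-of-range intervals are clamped to the nearest edge stair or dropped
#' per `config$oor_policy`.
#'
#' @param rri RR interval in seconds (> 0). Vectorised.
#' @param config An [rp_config].
#' @return Integer stair index (1-based), or `NA` for a dropped interval.
#' @export
assign_stair <- function(rri, config = rp_config()) {
  if (any(!is.finite(rri) | rri <= 0))
    rp_stop("RR intervals must be positive", "riskplot_input_error")
  e <- config$stair_edges
  K <- config$n_stairs
  k <- findInterval(rri, e, rightmost.closed = TRUE)
  if (config$oor_policy == "clamp") {
    k[k < 1L] <- 1L
    k[k > K] <- K
  } else {
    k[k < 1L | k > K] <- NA_integer_
  }
  as.integer(k)
}

#' Project one beat's token onto the risk plot
#'
#' Increments the occupancy of the target stair (or the dropped counter) and
#' recomputes the stuck flags.
#'
#' @param state An [rp_state].
#' @param rri RR interval in seconds.
#' @param config An [rp_config].
#' @return The updated `rp_state`.
#' @export
project_beat <- function(state, rri, config = rp_config()) {
  k <- assign_stair(rri, config)
  state$projected <- state$projected + 1L
  if (is.na(k)) {
    state$dropped <- state$dropped + 1L
  } else {
    state$occupancy[k] <- state$occupancy[k] + 1L
    state$stuck <- state$occupancy >= config$capacity
  }
  state
}

#' Drain each spring by one step
#'
#' Every non-stuck stair releases `min(drain_rate, occupancy)` tokens into
#' the valley; stuck stairs release nothing. Stuck flags are recomputed
#' afterwards (a stuck stair cannot fall below capacity, so within a window
#' stuck is absorbing).
#'
#' @param state An [rp_state].
#' @param config An [rp_config].
#' @return The updated `rp_state`.
#' @export
drain_step <- function(state, config = rp_config()) {
  movable <- pmin(config$drain_rate, state$occupancy)
  movable[state$stuck] <- 0L
  state$occupancy <- state$occupancy - movable
  state$valley <- state$valley + sum(movable)
  state$stuck <- state$occupancy >= config$capacity
  state
}

#' Stair occupancy histogram
#'
#' The per-stair token counts of a state, exposed for the index module.
#' Sums to `projected - valley - dropped`.
#'
#' @param state An [rp_state].
#' @return Integer vector of length `K`.
#' @export
occupancy_histogram <- function(state) {
  if (!inherits(state, "rp_state"))
    rp_stop("`state` must be an rp_state", "riskplot_input_error")
  state$occupancy
}

#' Run the risk-plot dynamics over an RR-interval series
#'
#' For each unflagged beat, one projection ([project_beat()]) followed by one
#' drainage step ([drain_step()]); flagged beats are skipped entirely and do
#' not advance the window clock. Every `window_beats` processed beats the
#' pre-reset state is recorded as that window's terminal state and the state
#' is reset to empty. A trailing incomplete window is reported with
#' `partial = TRUE`, never silently dropped.
#'
#' @param series An [rri_series].
#' @param mask Optional logical flag vector (e.g. from [quality_mask()]);
#'   `TRUE` marks intervals to skip. Default: nothing flagged.
#' @param config An [rp_config].
#' @param record `"windows"` keeps per-window summaries only; `"beats"` adds
#'   a post-drain snapshot per processed beat; `"events"` snapshots after
#'   both the projection and the drainage of every beat (used by the
#'   reference-simulator equivalence checks).
#' @return An object of class `rp_trace`: `windows` (data frame of window
#'   summaries), `counts` and `occupancy` (windows x stairs matrices of
#'   projection counts and terminal occupancies), `beats` (optional per-beat
#'   log with its own `occupancy` matrix), the `config`, and the beat times
#'   of the series.
#' @export
run_risk_plot <- function(series, mask = NULL, config = rp_config(),
                          record = c("windows", "beats", "events")) {
  record <- match.arg(record)
  if (!inherits(series, "rri_series"))
    rp_stop("`series` must be an rri_series", "riskplot_input_error")
  n <- length(series$intervals)
  if (n == 0L) rp_stop("empty RR-interval series", "riskplot_input_error")
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (length(mask) != n)
    rp_stop("`mask` must have one flag per interval", "riskplot_input_error")
  if (all(mask))
    rp_stop("all intervals are flagged; nothing to project", "riskplot_input_error")
  lvl <- match(record, c("windows", "beats", "events")) - 1L
  res <- .rp_engine(series$intervals, as.logical(mask), config$stair_edges,
                    config$drain_rate, config$capacity, config$window_beats,
                    config$oor_policy == "clamp", lvl)
  w <- res$windows
  windows <- data.frame(window = w$window, start_beat = w$start_beat,
                        end_beat = w$end_beat, n_beats = w$n_beats,
                        stuck_beats = w$stuck_beats, n_stuck = w$n_stuck,
                        projected = w$projected, valley = w$valley,
                        dropped = w$dropped, partial = w$partial == 1)
  windows$start_time <- series$beat_times[windows$start_beat]
  beats <- NULL
  if (!is.null(res$beats)) {
    b <- res$beats
    beats <- list(log = data.frame(beat = b$beat, window = b$window,
                                   phase = b$phase, stair = b$stair,
                                   valley = b$valley, projected = b$projected,
                                   dropped = b$dropped,
                                   any_stuck = b$any_stuck == 1),
                  occupancy = b$occupancy)
  }
  structure(list(windows = windows, counts = w$counts, occupancy = w$occupancy,
                 beats = beats, config = config, n_intervals = n,
                 n_flagged = sum(mask)),
            class = "rp_trace")
}

#' @export
print.rp_trace <- function(x, ...) {
  nw <- nrow(x$windows)
  cat(sprintf("<rp_trace> %d interval(s) (%d flagged), %d window(s)%s\n",
              x$n_intervals, x$n_flagged, nw,
              if (nw > 0 && x$windows$partial[nw]) " (last partial)" else ""))
  invisible(x)
}

#' Plot a risk-plot window
#'
#' Renders the stair landscape of one window: bars give each stair's
#' projection count over the window, stairs that ended the window stuck are
#' highlighted, and the annotation reports the valley count (tokens drained)
#' against the total projected.
#'
#' @param x An [run_risk_plot()] trace.
#' @param window Window number to draw (default: last).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.rp_trace <- function(x, window = nrow(x$windows), ...) {
  w <- x$windows[x$windows$window == window, ]
  if (nrow(w) == 0L)
    rp_stop(sprintf("no window %s in trace", window), "riskplot_input_error")
  counts <- x$counts[w$window, ]
  occ <- x$occupancy[w$window, ]
  e <- x$config$stair_edges
  mids <- (head(e, -1) + tail(e, -1)) / 2
  stuck <- occ >= x$config$capacity
  graphics::barplot(counts, names.arg = sprintf("%.2f", mids),
                    col = ifelse(stuck, "firebrick", "grey70"),
                    border = NA, space = 0,
                    xlab = "RR interval (s)", ylab = "tokens projected",
                    main = sprintf("Risk plot, window %d", w$window), ...)
  graphics::mtext(sprintf("valley %d / projected %d; %d stair(s) stuck",
                          w$valley, w$projected, sum(stuck)), side = 3,
                  line = 0.2, cex = 0.8)
  invisible(x)
}
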
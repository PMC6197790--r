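# Naive per-event reference simulator for the risk-plot dynamics.
#
# Deliberately written as a separate, token-by-token code path (explicit
# loops over stairs and tokens, no shared helpers with the production
# engine) so that it can serve as an independent oracle: on identical inputs
# the production engine must reproduce its event trace bit for bit. Event
# storage is preallocated; the dynamics themselves stay naive.

#' Reference risk-plot simulator
#'
#' Same dynamics as [run_risk_plot()], simulated one token at a time. Slow
#' by design; used to validate the production engine.
#'
#' @param series An [rri_series].
#' @param mask Optional logical flag vector; flagged beats are skipped.
#' @param config An [rp_config].
#' @return A list with `events` (one row per projection and per drainage
#'   step: `beat`, `phase`, `stair`, `valley`, `projected`, `dropped`,
#'   `any_stuck`), `event_occupancy` (events x stairs matrix), and
#'   `terminal_occupancy` (windows x stairs matrix, pre-reset state per
#'   window including a trailing partial window).
#' @export
rp_reference <- function(series, mask = NULL, config = rp_config()) {
  intervals <- series$intervals
  n <- length(intervals)
  if (is.null(mask)) mask <- rep(FALSE, n)
  edges <- config$stair_edges
  K <- length(edges) - 1L
  d <- config$drain_rate
  C <- config$capacity
  W <- config$window_beats
  clamp <- config$oor_policy == "clamp"

  occ <- rep(0L, K)
  valley <- 0L; projected <- 0L; dropped <- 0L
  beats_in_window <- 0L

  n_ev <- 2L * sum(!mask)
  ev_beat <- integer(n_ev); ev_phase <- character(n_ev)
  ev_stair <- integer(n_ev); ev_valley <- integer(n_ev)
  ev_projected <- integer(n_ev); ev_dropped <- integer(n_ev)
  ev_anystuck <- logical(n_ev)
  ev_occ <- matrix(0L, n_ev, K)
  term_list <- list()
  ev <- 0L

  for (i in seq_len(n)) {
    if (mask[i]) next
    x <- intervals[i]

    # find the landing stair by walking the edges
    stair <- NA_integer_
    for (k in seq_len(K)) {
      if (x >= edges[k] && x < edges[k + 1L]) { stair <- k; break }
    }
    if (is.na(stair) && x == edges[K + 1L]) stair <- K  # right edge closed
    if (is.na(stair) && clamp) stair <- if (x < edges[1L]) 1L else K

    projected <- projected + 1L
    if (is.na(stair)) {
      dropped <- dropped + 1L
    } else {
      occ[stair] <- occ[stair] + 1L  # one token lands
    }
    any_now <- FALSE
    for (k in seq_len(K)) if (occ[k] >= C) { any_now <- TRUE; break }
    ev <- ev + 1L
    ev_beat[ev] <- i; ev_phase[ev] <- "project"; ev_stair[ev] <- stair
    ev_valley[ev] <- valley; ev_projected[ev] <- projected
    ev_dropped[ev] <- dropped; ev_anystuck[ev] <- any_now
    ev_occ[ev, ] <- occ

    # springs: each stair not currently stuck throws up to d tokens,
    # one at a time
    for (k in seq_len(K)) {
      if (occ[k] >= C) next
      thrown <- 0L
      while (thrown < d && occ[k] > 0L) {
        occ[k] <- occ[k] - 1L
        valley <- valley + 1L
        thrown <- thrown + 1L
      }
    }
    any_now <- FALSE
    for (k in seq_len(K)) if (occ[k] >= C) { any_now <- TRUE; break }
    ev <- ev + 1L
    ev_beat[ev] <- i; ev_phase[ev] <- "drain"; ev_stair[ev] <- stair
    ev_valley[ev] <- valley; ev_projected[ev] <- projected
    ev_dropped[ev] <- dropped; ev_anystuck[ev] <- any_now
    ev_occ[ev, ] <- occ

    beats_in_window <- beats_in_window + 1L
    if (beats_in_window == W) {
      term_list[[length(term_list) + 1L]] <- occ
      occ <- rep(0L, K)
      valley <- 0L; projected <- 0L; dropped <- 0L
      beats_in_window <- 0L
    }
  }
  if (beats_in_window > 0L) term_list[[length(term_list) + 1L]] <- occ

  list(events = data.frame(beat = ev_beat, phase = ev_phase, stair = ev_stair,
                           valley = ev_valley, projected = ev_projected,
                           dropped = ev_dropped, any_stuck = ev_anystuck),
       event_occupancy = ev_occ,
       terminal_occupancy = do.call(rbind, term_list))
}
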
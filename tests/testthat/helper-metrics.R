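# Shared evaluation helpers for the test suite.

# Greedy one-to-one matching of detected peaks to truth peaks within a time
# tolerance; returns sensitivity and positive predictive value.
match_peaks <- function(detected, truth, fs, tol_s = 0.04) {
  used <- logical(length(detected))
  tp <- 0L
  for (t in truth) {
    ok <- which(!used & abs(detected - t) <= tol_s * fs)
    if (length(ok) > 0L) {
      used[ok[which.min(abs(detected[ok] - t))]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(sensitivity = tp / length(truth), ppv = tp / length(detected))
}

# Mann-Whitney AUC: probability that a randomly chosen positive scores
# higher than a randomly chosen negative (ties count half).
rank_auc <- function(scores_pos, scores_neg) {
  r <- rank(c(scores_pos, scores_neg))
  n1 <- length(scores_pos); n0 <- length(scores_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Random risk-plot configuration + interval stream for fuzzing the engine
# against the reference simulator.
random_rp_case <- function(n_beats) {
  K <- sample(4:12, 1)
  lo <- runif(1, 0.25, 0.5)
  edges <- lo + cumsum(runif(K, 0.02, 0.2))
  edges <- c(lo, edges)
  d <- sample(0:3, 1)
  C <- d + sample(1:8, 1)
  list(series = rri_series(runif(n_beats, 0.2, 2.2)),
       mask = runif(n_beats) < 0.05,
       config = rp_config(stair_edges = edges, drain_rate = d, capacity = C,
                          window_beats = sample(c(25, 60, 100, 400), 1),
                          oor_policy = sample(c("clamp", "drop"), 1)))
}

# Amplitude of the `freq` Hz component of x, by least squares on the
# quadrature pair (robust to spectral leakage from finite duration).
tone_amplitude <- function(x, fs, freq) {
  t <- (seq_along(x) - 1) / fs
  fit <- stats::lm(x ~ sin(2 * pi * freq * t) + cos(2 * pi * freq * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}
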
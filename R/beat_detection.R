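# R-peak detection and RR-interval construction.

#' Detect R peaks in a (preprocessed) ECG
#'
#' A Pan-Tompkins-style chain: zero-phase 5-15 Hz band-pass, derivative,
#' squaring, 150 ms moving-window integration, adaptive dual thresholds with
#' a 200 ms refractory period and a search-back pass for missed beats. Peak
#' positions are refined to the local maximum of the input samples, so on
#' clean records detected indices sit on the R wave itself. The chain uses
#' only relative thresholds, so detection is invariant to positive amplitude
#' scaling.
#'
#' @param record An [ecg_record], ideally already notch-filtered/denoised.
#'   Must be at least 2 s long.
#' @param refractory Minimum separation between accepted peaks in seconds.
#' @return A [peak_annotation] (possibly with zero peaks, e.g. on a flat
#'   line).
#' @export
detect_r_peaks <- function(record, refractory = 0.2) {
  if (!inherits(record, "ecg_record"))
    rp_stop("`record` must be an ecg_record", "riskplot_input_error")
  fs <- record$fs
  x <- record$samples
  n <- length(x)
  if (n < 2 * fs)
    rp_stop("record shorter than 2 s; too short for beat detection",
            "riskplot_input_error")
  if (stats::sd(x) == 0)
    return(peak_annotation(integer(0), fs))

  # band-pass 5-15 Hz (QRS energy band), zero phase
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)

  # derivative -> squaring -> moving integration (150 ms)
  dv <- c(0, diff(xf)) * fs
  sq <- dv^2
  wi <- max(3L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / wi, wi), sides = 2))
  integ[is.na(integ)] <- 0

  # candidate local maxima of the integrated energy
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  cand <- cand[integ[cand] > 0]
  if (length(cand) == 0L) return(peak_annotation(integer(0), fs))

  refr <- as.integer(round(refractory * fs))
  init <- integ[seq_len(min(n, 2L * round(fs)))]
  spk <- max(init)          # running signal-peak estimate
  npk <- mean(init)         # running noise-peak estimate
  thr <- npk + 0.25 * (spk - npk)

  accepted <- integer(0)
  last <- -Inf
  rr_hist <- numeric(0)
  for (i in cand) {
    p <- integ[i]
    if (i - last < refr) next
    if (p > thr) {
      # search-back: if the gap since the last beat is long, rescue the
      # largest candidate inside it at half threshold
      if (length(rr_hist) >= 4L && length(accepted) > 0L) {
        expected <- stats::median(tail(rr_hist, 8L))
        if (i - last > 1.66 * expected) {
          inside <- cand[cand > last + refr & cand < i - refr]
          if (length(inside) > 0L) {
            j <- inside[which.max(integ[inside])]
            if (integ[j] > 0.5 * thr) {
              rr_hist <- c(rr_hist, j - last)
              accepted <- c(accepted, j)
              last <- j
            }
          }
        }
      }
      if (length(accepted) > 0L) rr_hist <- c(rr_hist, i - last)
      accepted <- c(accepted, i)
      last <- i
      spk <- 0.125 * p + 0.875 * spk
    } else {
      npk <- 0.125 * p + 0.875 * npk
    }
    thr <- npk + 0.25 * (spk - npk)
  }
  if (length(accepted) == 0L) return(peak_annotation(integer(0), fs))

  # refine each detection to the R apex: local maximum of the input samples
  # inside +/- 100 ms of the integration peak (the T apex sits further out)
  w <- as.integer(round(0.10 * fs))
  peaks <- vapply(accepted, function(i) {
    lo <- max(1L, as.integer(i) - w); hi <- min(n, as.integer(i) + w)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refinement can merge neighbours; re-impose the refractory period keeping
  # the larger apex
  if (length(peaks) > 1L) {
    keep <- logical(length(peaks))
    keep[1] <- TRUE
    lastk <- 1L
    for (k in 2L:length(peaks)) {
      if (peaks[k] - peaks[lastk] >= refr) {
        keep[k] <- TRUE
        lastk <- k
      } else if (x[peaks[k]] > x[peaks[lastk]]) {
        keep[lastk] <- FALSE
        keep[k] <- TRUE
        lastk <- k
      }
    }
    peaks <- peaks[keep]
  }
  peak_annotation(peaks, fs)
}

#' RR intervals from an R-peak annotation
#'
#' `intervals[i] = (indices[i + 1] - indices[i]) / fs`; beat times are
#' anchored at the first peak, `beat_times[1] = (indices[1] - 1) / fs`.
#'
#' @param peaks A [peak_annotation] with at least two peaks.
#' @return An [rri_series].
#' @export
compute_rri <- function(peaks) {
  if (!inherits(peaks, "peak_annotation"))
    rp_stop("`peaks` must be a peak_annotation", "riskplot_input_error")
  if (length(peaks$indices) < 2L)
    rp_stop("need at least 2 peaks to form RR intervals", "riskplot_input_error")
  rri_series(diff(peaks$indices) / peaks$fs,
             t0 = (peaks$indices[1] - 1L) / peaks$fs)
}

#' Flag physiologically implausible RR intervals
#'
#' An interval is flagged when it falls outside `range` (defaults 0.2-3.0 s)
#' or differs from the running median of the surrounding 11 intervals by more
#' than `rel_tol` (default 50%). Flagged intervals are retained in the series
#' but excluded from risk-plot projection, guarding the dynamics against
#' mis-detections without silently altering the record.
#'
#' @param series An [rri_series].
#' @param range Plausible interval range in seconds.
#' @param rel_tol Maximum relative deviation from the local median.
#' @return A logical vector, `TRUE` where the interval is suspect.
#' @export
quality_mask <- function(series, range = c(0.2, 3.0), rel_tol = 0.5) {
  if (!inherits(series, "rri_series"))
    rp_stop("`series` must be an rri_series", "riskplot_input_error")
  x <- series$intervals
  flags <- x < range[1] | x > range[2]
  if (length(x) >= 3L) {
    k <- min(11L, length(x) - (length(x) + 1L) %% 2L)  # largest odd <= min(11, n)
    med <- stats::runmed(x, k, endrule = "median")
    flags <- flags | abs(x - med) / med > rel_tol
  }
  as.logical(flags)
}
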
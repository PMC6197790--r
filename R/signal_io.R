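# Domain containers and file I/O for ECG records, R-peak annotations, and
# RR-interval series.
#
# Conventions: sample indices are 1-based (R idiom); amplitudes are millivolts;
# times are seconds; beat_times[1] anchors the record-local clock.

#' Construct an ECG record
#'
#' A single-channel ECG: amplitude samples (mV) at a fixed sampling rate,
#' optionally carrying ground-truth R-peak sample indices (1-based), e.g. from
#' an annotation file or from the synthetic generator.
#'
#' @param samples Numeric vector of amplitudes in millivolts. Must be finite.
#' @param fs Sampling frequency in Hz (> 0).
#' @param t0 Start offset of the first sample in seconds.
#' @param label Channel name.
#' @param truth_peaks Optional integer vector of annotated R-peak sample
#'   indices (1-based, strictly increasing, within the record).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, t0 = 0, label = "ECG", truth_peaks = NULL) {
  samples <- as.numeric(samples)
  if (!is_number(fs) || fs <= 0)
    rp_stop("`fs` must be a single positive number", "riskplot_input_error")
  if (length(samples) == 0L || !all(is.finite(samples)))
    rp_stop("`samples` must be non-empty and finite (no NA/NaN/Inf)",
            "riskplot_input_error")
  if (!is_number(t0))
    rp_stop("`t0` must be a single finite number", "riskplot_input_error")
  if (!is.null(truth_peaks)) {
    truth_peaks <- as.integer(truth_peaks)
    if (any(truth_peaks < 1L) || any(truth_peaks > length(samples)) ||
        (length(truth_peaks) > 1L && any(diff(truth_peaks) <= 0L)))
      rp_stop("`truth_peaks` must be strictly increasing indices within the record",
              "riskplot_input_error")
  }
  structure(list(samples = samples, fs = fs, t0 = t0,
                 label = as.character(label)[1], truth_peaks = truth_peaks),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d samples @ %g Hz (%.1f s)%s\n",
              x$label, length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.null(x$truth_peaks)) ""
              else sprintf(", %d annotated beats", length(x$truth_peaks))))
  invisible(x)
}

#' Construct an R-peak annotation
#'
#' @param indices Strictly increasing 1-based sample indices of R peaks.
#' @param fs Sampling frequency (Hz) of the source record.
#' @return An object of class `peak_annotation`.
#' @export
peak_annotation <- function(indices, fs) {
  indices <- as.integer(indices)
  if (!is_number(fs) || fs <= 0)
    rp_stop("`fs` must be a single positive number", "riskplot_input_error")
  if (any(indices < 1L) || (length(indices) > 1L && any(diff(indices) <= 0L)))
    rp_stop("peak indices must be positive and strictly increasing",
            "riskplot_input_error")
  structure(list(indices = indices, fs = fs), class = "peak_annotation")
}

#' @export
print.peak_annotation <- function(x, ...) {
  cat(sprintf("<peak_annotation> %d peaks @ %g Hz\n", length(x$indices), x$fs))
  invisible(x)
}

#' Construct an RR-interval series
#'
#' The heart-rate-variability signal: successive RR intervals in seconds with
#' cumulative beat onset times, `beat_times[i + 1] = beat_times[i] +
#' intervals[i]` and `beat_times[1] = t0`.
#'
#' @param intervals Numeric vector of RR intervals in seconds (all > 0).
#' @param t0 Time of the first beat (s); defaults to 0.
#' @return An object of class `rri_series` with elements `intervals` and
#'   `beat_times` (length `length(intervals) + 1`).
#' @export
rri_series <- function(intervals, t0 = 0) {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L)
    rp_stop("`intervals` must be non-empty", "riskplot_input_error")
  if (!all(is.finite(intervals)) || any(intervals <= 0))
    rp_stop("all RR intervals must be finite and > 0", "riskplot_input_error")
  structure(list(intervals = intervals,
                 beat_times = t0 + c(0, cumsum(intervals))),
            class = "rri_series")
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("<rri_series> %d intervals, %.1f s, mean RR %.3f s, SDNN %.1f ms\n",
              length(x$intervals), sum(x$intervals), mean(x$intervals),
              1000 * stats::sd(x$intervals)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# CSV ECG (time,amplitude)

# Maximum relative deviation of a time step from the median step before the
# sampling grid is rejected as non-uniform.
.csv_jitter_tol <- 1e-6

read_ecg_csv <- function(path) {
  dat <- tryCatch(utils::read.csv(path, header = TRUE),
                  error = function(e) rp_stop(
                    sprintf("cannot read '%s': %s", path, conditionMessage(e)),
                    "riskplot_io_error"))
  if (ncol(dat) < 2L || nrow(dat) < 2L)
    rp_stop("ECG csv needs two columns (time s, amplitude mV) and >= 2 rows",
            "riskplot_format_error")
  tm <- as.numeric(dat[[1]]); amp <- as.numeric(dat[[2]])
  if (any(!is.finite(tm)) || any(!is.finite(amp)))
    rp_stop("ECG csv contains non-numeric or non-finite values",
            "riskplot_format_error")
  dt <- diff(tm)
  step <- stats::median(dt)
  if (step <= 0 || any(abs(dt - step) > .csv_jitter_tol * step))
    rp_stop("ECG csv time column is not a uniform increasing grid (relative jitter > 1e-6)",
            "riskplot_format_error")
  fs <- 1 / step
  if (abs(fs - round(fs)) < 1e-4) fs <- round(fs)  # undo decimal rounding of time stamps
  ecg_record(amp, fs = fs, t0 = tm[1])
}

write_ecg_csv <- function(record, path) {
  con <- tryCatch(file(path, "wt"),
                  error = function(e) rp_stop(
                    sprintf("cannot open '%s' for writing", path), "riskplot_io_error"))
  on.exit(close(con))
  tm <- record$t0 + (seq_along(record$samples) - 1) / record$fs
  writeLines("time,amplitude", con)
  writeLines(sprintf("%.9f,%.9g", tm, record$samples), con)
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Minimal WFDB support: single-signal format 16 (.hea + .dat) plus the MIT
# annotation stream (.atr, beat code 'N'). No installed package provides
# WFDB I/O in this stack, so the subset needed here is implemented directly.

.wfdb_gain <- 2000L  # ADC units per mV; int16 range then covers +/- 16 mV

.wfdb_base <- function(path) sub("\\.(hea|dat|atr)$", "", path)

write_ecg_wfdb <- function(record, path) {
  base <- .wfdb_base(path)
  name <- basename(base)
  adc <- as.integer(round(record$samples * .wfdb_gain))
  if (any(adc > 32767L | adc < -32768L))
    rp_stop("amplitude exceeds the int16 range of WFDB format 16 at gain 2000/mV",
            "riskplot_format_error")
  hea <- c(sprintf("%s 1 %.10g %d", name, record$fs, length(adc)),
           sprintf("%s.dat 16 %d/mV 16 0 %d %d 0 %s",
                   name, .wfdb_gain, adc[1],
                   .int16_checksum(adc), record$label))
  ok <- tryCatch({
    writeLines(hea, paste0(base, ".hea"))
    con <- file(paste0(base, ".dat"), "wb")
    writeBin(adc, con, size = 2L, endian = "little")
    close(con)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) rp_stop(sprintf("cannot write WFDB record '%s'", base), "riskplot_io_error")
  if (!is.null(record$truth_peaks))
    write_wfdb_annotation(record$truth_peaks, paste0(base, ".atr"))
  invisible(NULL)
}

.int16_checksum <- function(adc) {
  s <- sum(as.numeric(adc)) %% 65536
  as.integer(if (s > 32767) s - 65536 else s)
}

read_ecg_wfdb <- function(path) {
  base <- .wfdb_base(path)
  hea_path <- paste0(base, ".hea")
  if (!file.exists(hea_path))
    rp_stop(sprintf("WFDB header '%s' not found", hea_path), "riskplot_io_error")
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 4L)
    rp_stop("malformed WFDB header record line", "riskplot_format_error")
  fs <- as.numeric(rec[3]); nsamp <- as.integer(rec[4])
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  fmt <- sig[2]
  if (fmt != "16")
    rp_stop(sprintf("unsupported WFDB signal format '%s' (only 16)", fmt),
            "riskplot_format_error")
  gain_field <- sub("/.*$", "", sig[3])
  baseline <- 0
  if (grepl("\\(", gain_field)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    gain_field <- sub("\\(.*$", "", gain_field)
  }
  gain <- as.numeric(gain_field)
  if (!is.finite(gain) || gain == 0) gain <- 200  # WFDB default
  label <- if (length(sig) >= 9L) paste(sig[9:length(sig)], collapse = " ") else "ECG"
  dat_path <- file.path(dirname(base), sig[1])
  con <- tryCatch(file(dat_path, "rb"),
                  error = function(e) rp_stop(
                    sprintf("cannot open WFDB signal file '%s'", dat_path),
                    "riskplot_io_error"))
  adc <- readBin(con, integer(), n = nsamp, size = 2L, signed = TRUE,
                 endian = "little")
  close(con)
  if (length(adc) != nsamp)
    rp_stop("WFDB signal file shorter than header sample count",
            "riskplot_format_error")
  peaks <- NULL
  atr_path <- paste0(base, ".atr")
  if (file.exists(atr_path)) peaks <- read_wfdb_annotation(atr_path)
  ecg_record((adc - baseline) / gain, fs = fs, label = label,
             truth_peaks = peaks)
}

# MIT annotation stream: 2-byte little-endian words, type code in the top 6
# bits, time increment (samples since previous annotation) in the low 10;
# increments > 1023 use a SKIP (code 59) word followed by a 4-byte interval in
# PDP-11 word order. Stream ends with a zero word.
write_wfdb_annotation <- function(indices, path) {
  words <- integer(0)
  prev <- 0
  for (idx in indices) {
    delta <- (idx - 1L) - prev   # annotations store 0-based sample numbers
    prev <- idx - 1L
    if (delta > 1023L) {
      words <- c(words, bitwShiftL(59L, 10L),
                 bitwAnd(bitwShiftR(delta, 16L), 0xFFFFL),
                 bitwAnd(delta, 0xFFFFL))
      delta <- 0L
    }
    words <- c(words, bitwOr(bitwShiftL(1L, 10L), delta))  # code 1 = 'N'
  }
  words <- c(words, 0L)
  words <- ifelse(words > 32767L, words - 65536L, words)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) rp_stop(
                    sprintf("cannot open '%s' for writing", path), "riskplot_io_error"))
  writeBin(as.integer(words), con, size = 2L, endian = "little")
  close(con)
  invisible(NULL)
}

read_wfdb_annotation <- function(path) {
  con <- file(path, "rb")
  raw_words <- readBin(con, integer(), n = file.size(path) %/% 2L, size = 2L,
                       signed = FALSE, endian = "little")
  close(con)
  indices <- integer(0)
  tt <- 0L
  i <- 1L
  while (i <= length(raw_words)) {
    w <- raw_words[i]
    code <- bitwShiftR(w, 10L)
    delta <- bitwAnd(w, 1023L)
    if (w == 0L) break
    if (code == 59L) {  # SKIP: 4-byte interval follows
      tt <- tt + bitwShiftL(raw_words[i + 1L], 16L) + raw_words[i + 2L]
      i <- i + 3L
      next
    }
    tt <- tt + delta
    if (code >= 1L && code <= 49L) indices <- c(indices, tt + 1L)
    i <- i + 1L
  }
  indices
}

# ---------------------------------------------------------------------------
# Public readers/writers

#' Read an ECG record
#'
#' Reads a single-lead ECG from either a two-column CSV (`time` in seconds on
#' a uniform grid, `amplitude` in mV) or a minimal WFDB record (format 16
#' `.dat` + `.hea`; a companion `.atr` annotation stream, if present,
#' populates `truth_peaks`).
#'
#' @param path File path. For WFDB, the record name with or without extension.
#' @param format `"csv"` or `"wfdb"`.
#' @return An [ecg_record].
#' @export
read_ecg <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv" && !file.exists(path))
    rp_stop(sprintf("file '%s' not found", path), "riskplot_io_error")
  switch(format, csv = read_ecg_csv(path), wfdb = read_ecg_wfdb(path))
}

#' Write an ECG record
#'
#' Inverse of [read_ecg()]: CSV preserves amplitudes to printed precision and
#' the time offset `t0`; WFDB format 16 quantises amplitudes to 1/2000 mV and
#' stores `truth_peaks` (if any) as an `.atr` annotation stream.
#'
#' @param record An [ecg_record].
#' @param path Output path (record base name for WFDB).
#' @param format `"csv"` or `"wfdb"`.
#' @export
write_ecg <- function(record, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (!inherits(record, "ecg_record"))
    rp_stop("`record` must be an ecg_record", "riskplot_input_error")
  switch(format, csv = write_ecg_csv(record, path),
         wfdb = write_ecg_wfdb(record, path))
  invisible(NULL)
}

#' Read an RR-interval series
#'
#' Plain-text dialect: one interval in seconds per line; blank lines and
#' lines starting with `#` are ignored. Beat times are reconstructed as the
#' cumulative sum with `beat_times[1] = 0`.
#'
#' @param path File path.
#' @return An [rri_series].
#' @export
read_rri <- function(path) {
  if (!file.exists(path))
    rp_stop(sprintf("file '%s' not found", path), "riskplot_io_error")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  vals <- suppressWarnings(as.numeric(lines[keep]))
  lineno <- which(keep)
  if (length(vals) == 0L)
    rp_stop(sprintf("'%s' contains no intervals", path), "riskplot_format_error")
  bad <- which(!is.finite(vals) | vals <= 0)
  if (length(bad) > 0L)
    rp_stop(sprintf("invalid RR interval '%s' at line %d of '%s' (must be a positive number)",
                    trimws(lines[lineno[bad[1]]]), lineno[bad[1]], path),
            "riskplot_format_error")
  rri_series(vals)
}

#' Write an RR-interval series
#'
#' @param series An [rri_series].
#' @param path Output path. Intervals are written one per line with nine
#'   decimals, so a write/read round trip is exact to well below 1e-6 s.
#' @export
write_rri <- function(series, path) {
  if (!inherits(series, "rri_series"))
    rp_stop("`series` must be an rri_series", "riskplot_input_error")
  ok <- tryCatch({ writeLines(sprintf("%.9f", series$intervals), path); TRUE },
                 error = function(e) FALSE)
  if (!ok) rp_stop(sprintf("cannot write '%s'", path), "riskplot_io_error")
  invisible(NULL)
}
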
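# Pipeline orchestration: configuration file handling, the analyze/rri/synth
# entry points used by the command-line tool, and report writing. Every run
# emits a manifest echoing the full effective configuration so it can be
# reproduced exactly; dropped and flagged counts are always reported.

.default_config <- function() {
  list(
    preprocess = list(mains_freq = 50, notch_q = 30, wavelet = "db4",
                      level = 4, detail_levels = c(1, 2)),
    detection = list(include_flagged = FALSE, refractory = 0.2),
    rp = list(stair_min = 0.3, stair_max = 1.5, stair_width = 0.01,
              drain_rate = 1, capacity = 8, window_beats = 300,
              oor_policy = "clamp"),
    index = list(weights = list(concentration = 0.4, stuck = 0.4,
                                throughput = 0.2),
                 thresholds = list(amber = 0.20, red = 0.25)),
    output = list(plots = TRUE),
    log_level = "info")
}

# Strict recursive merge: every key in `user` must exist in `defaults`.
.merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    if (!key %in% names(defaults))
      rp_stop(sprintf("unknown configuration key '%s'",
                      paste(c(path, key), collapse = ".")),
              "riskplot_config_error")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        rp_stop(sprintf("configuration key '%s' must be a mapping",
                        paste(c(path, key), collapse = ".")),
                "riskplot_config_error")
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]],
                                       c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file with sections `preprocess`, `detection`, `rp`, `index`,
#' `output` and `log_level`, merges it over the package defaults, and
#' validates every subsection. Unknown keys are rejected (a typo should fail
#' loudly, not silently fall back to a default).
#'
#' @param file Path to a YAML file, or `NULL` for pure defaults.
#' @return An object of class `pipeline_config`: the merged configuration
#'   plus ready-built `preprocess_config`, `rp_config`, weight and threshold
#'   objects.
#' @export
pipeline_config <- function(file = NULL) {
  cfg <- .default_config()
  if (!is.null(file)) {
    if (!file.exists(file))
      rp_stop(sprintf("config file '%s' not found", file), "riskplot_io_error")
    user <- tryCatch(yaml::read_yaml(file), error = function(e)
      rp_stop(sprintf("cannot parse config '%s': %s", file,
                      conditionMessage(e)), "riskplot_config_error"))
    if (!is.null(user)) cfg <- .merge_config(cfg, user)
  }
  pp <- preprocess_config(mains_freq = cfg$preprocess$mains_freq,
                          notch_q = cfg$preprocess$notch_q,
                          wavelet = cfg$preprocess$wavelet,
                          level = cfg$preprocess$level,
                          detail_levels = unlist(cfg$preprocess$detail_levels))
  rp <- cfg$rp
  if (!is_number(rp$stair_width) || rp$stair_width <= 0 ||
      !is_number(rp$stair_min) || !is_number(rp$stair_max) ||
      rp$stair_max <= rp$stair_min)
    rp_stop("rp.stair_min/stair_max/stair_width do not define a valid stair grid",
            "riskplot_config_error")
  edges <- seq(rp$stair_min, rp$stair_max, by = rp$stair_width)
  rpc <- rp_config(stair_edges = edges, drain_rate = rp$drain_rate,
                   capacity = rp$capacity, window_beats = rp$window_beats,
                   oor_policy = rp$oor_policy)
  wts <- risk_weights(concentration = cfg$index$weights$concentration,
                      stuck = cfg$index$weights$stuck,
                      throughput = cfg$index$weights$throughput)
  thr <- alarm_thresholds(amber = cfg$index$thresholds$amber,
                          red = cfg$index$thresholds$red)
  if (!isTRUE(cfg$output$plots) && !isFALSE(cfg$output$plots))
    rp_stop("output.plots must be true or false", "riskplot_config_error")
  if (!cfg$log_level %in% c("info", "quiet"))
    rp_stop("log_level must be 'info' or 'quiet'", "riskplot_config_error")
  structure(list(raw = cfg, preprocess = pp, rp = rpc, weights = wts,
                 thresholds = thr,
                 include_flagged = isTRUE(cfg$detection$include_flagged),
                 refractory = cfg$detection$refractory,
                 plots = isTRUE(cfg$output$plots),
                 log_level = cfg$log_level),
            class = "pipeline_config")
}

.as_pipeline_config <- function(config) {
  if (is.null(config)) return(pipeline_config())
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config)) return(pipeline_config(config))
  rp_stop("`config` must be NULL, a pipeline_config, or a YAML file path",
          "riskplot_config_error")
}

.log_stage <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "info")) message(sprintf(fmt, ...))
  invisible(NULL)
}

# Shared back half of analyze/rri: mask -> risk plot -> index -> reports.
.run_rp_stage <- function(series, cfg, out_dir, source_desc,
                          extra_manifest = list()) {
  mask <- quality_mask(series)
  if (cfg$include_flagged) mask <- rep(FALSE, length(mask))
  .log_stage(cfg, "quality mask: %d of %d intervals flagged",
             sum(mask), length(mask))
  if (all(mask))
    rp_stop("all intervals flagged by the quality mask", "riskplot_input_error")
  trace <- run_risk_plot(series, mask = mask, config = cfg$rp)
  complete <- sum(!trace$windows$partial)
  .log_stage(cfg, "risk plot: %d window(s) (%d complete)",
             nrow(trace$windows), complete)
  if (complete == 0L)
    message(sprintf("note: no complete window (%d beats per window needed); reporting partial window only",
                    cfg$rp$window_beats))
  report <- if (complete > 0L)
    risk_series(trace, cfg$weights, cfg$thresholds)
  else
    window_index(trace, trace$windows$window[1], cfg$weights, cfg$thresholds)
  disp <- dispersion_summary(series, cfg$rp$window_beats,
                             mask = if (cfg$include_flagged) NULL else mask)
  report$sdnn <- disp$sdnn[match(report$window, disp$window)]

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  windows_csv <- file.path(out_dir, "windows.csv")
  utils::write.csv(report, windows_csv, row.names = FALSE, quote = FALSE)
  alarms_log <- file.path(out_dir, "alarms.log")
  writeLines(c(sprintf("alarm summary: %d green, %d amber, %d red",
                       sum(report$alarm == "green"), sum(report$alarm == "amber"),
                       sum(report$alarm == "red")),
               sprintf("t=%.1fs window=%d risk=%.3f sdnn=%.4f level=%s%s",
                       report$start_time, report$window, report$risk,
                       report$sdnn, toupper(report$alarm),
                       ifelse(report$partial, " (partial)", ""))),
             alarms_log)
  fig <- NULL
  if (cfg$plots) {
    fig <- file.path(out_dir, "riskplot.png")
    grDevices::png(fig, width = 900, height = 500)
    plot(trace)
    grDevices::dev.off()
  }
  manifest <- c(list(tool = "riskplot",
                     version = as.character(utils::packageVersion("riskplot")),
                     source = source_desc,
                     n_intervals = length(series$intervals),
                     n_flagged = sum(mask),
                     n_dropped = sum(trace$windows$dropped),
                     n_windows = nrow(trace$windows),
                     n_complete_windows = complete),
                extra_manifest, list(config = cfg$raw))
  manifest_yaml <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_yaml)
  invisible(list(report = report, trace = trace, series = series, mask = mask,
                 paths = list(windows = windows_csv, alarms = alarms_log,
                              figure = fig, manifest = manifest_yaml)))
}

#' Analyze an ECG recording end to end
#'
#' The full monitoring pipeline: read, notch filter, wavelet denoise, R-peak
#' detection, RR-interval construction, quality masking, risk-plot dynamics,
#' per-window risk index with alarms. Writes `windows.csv`, `alarms.log`,
#' `riskplot.png` (unless disabled) and `manifest.yaml` to `out_dir`.
#'
#' @param input ECG file path (see [read_ecg()]).
#' @param out_dir Output directory (created if needed).
#' @param format `"csv"` or `"wfdb"`.
#' @param config `NULL` (defaults), a YAML file path, or a
#'   [pipeline_config()].
#' @return Invisibly, a list with the per-window `report`, the `trace`, the
#'   RR `series`, the quality `mask`, and output `paths`.
#' @export
run_analyze <- function(input, out_dir, format = c("csv", "wfdb"),
                        config = NULL) {
  format <- match.arg(format)
  cfg <- .as_pipeline_config(config)
  record <- read_ecg(input, format)
  .log_stage(cfg, "read: %d samples at %g Hz from %s",
             length(record$samples), record$fs, input)
  record <- notch_filter(record, cfg$preprocess)
  .log_stage(cfg, "notch: %g Hz removed", cfg$preprocess$mains_freq)
  record <- wavelet_denoise(record, cfg$preprocess)
  .log_stage(cfg, "denoise: %s level %d", cfg$preprocess$wavelet,
             cfg$preprocess$level)
  peaks <- detect_r_peaks(record, refractory = cfg$refractory)
  .log_stage(cfg, "detection: %d R peaks", length(peaks$indices))
  series <- compute_rri(peaks)
  .log_stage(cfg, "rri: %d intervals", length(series$intervals))
  .run_rp_stage(series, cfg, out_dir, source_desc = input,
                extra_manifest = list(format = format,
                                      n_samples = length(record$samples),
                                      fs = record$fs,
                                      n_peaks = length(peaks$indices)))
}

#' Analyze a precomputed RR-interval file
#'
#' Entry point bypassing the ECG stages: reads a plain-text interval list
#' (see [read_rri()]) and runs quality masking, the risk-plot dynamics and
#' the risk index, writing the same report bundle as [run_analyze()].
#'
#' @param input RR-interval file path.
#' @inheritParams run_analyze
#' @return Invisibly, the same structure as [run_analyze()].
#' @export
run_rri <- function(input, out_dir, config = NULL) {
  cfg <- .as_pipeline_config(config)
  series <- read_rri(input)
  .log_stage(cfg, "read: %d intervals from %s", length(series$intervals), input)
  .run_rp_stage(series, cfg, out_dir, source_desc = input)
}

#' Generate synthetic fixtures
#'
#' Writes either a labelled cohort of RR-interval files (plus
#' `cohort_manifest.csv`) or a single profile's RR series, optionally
#' rendered as a WFDB ECG record with annotated truth peaks. Deterministic
#' for a given seed: repeated invocation produces identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort Integer vector `c(n_healthy, n_risk)`, or `NULL` for a
#'   single profile.
#' @param profile A [synth_profile()] used when `cohort` is `NULL`.
#' @param ecg If `TRUE`, also render the single profile as a WFDB record
#'   (`ecg.hea`/`ecg.dat`/`ecg.atr`).
#' @param seed Master seed (overrides the profile's seed).
#' @param n_beats Beats per cohort subject.
#' @return Invisibly, a character vector of the files written.
#' @export
run_synth <- function(out_dir, cohort = NULL, profile = synth_profile(),
                      ecg = FALSE, seed = 1L, n_beats = 3300L) {
  if (isTRUE(ecg) && !is.null(cohort))
    rp_stop("`ecg` rendering is only available for a single profile, not a cohort",
            "riskplot_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  if (!is.null(cohort)) {
    if (length(cohort) != 2L || !is_count(cohort[1], 1L) || !is_count(cohort[2], 1L))
      rp_stop("`cohort` must be c(n_healthy, n_risk) with both >= 1",
              "riskplot_config_error")
    ch <- generate_cohort(cohort[1], cohort[2], seed = seed, n_beats = n_beats)
    for (i in seq_along(ch$series)) {
      f <- file.path(out_dir, sprintf("%s_%s.rri", ch$manifest$subject[i],
                                      ch$manifest$label[i]))
      write_rri(ch$series[[i]], f)
      written <- c(written, f)
    }
    mf <- file.path(out_dir, "cohort_manifest.csv")
    utils::write.csv(ch$manifest, mf, row.names = FALSE, quote = FALSE)
    written <- c(written, mf)
  } else {
    profile$seed <- as.integer(seed)
    series <- generate_rri(profile)
    f <- file.path(out_dir, "profile.rri")
    write_rri(series, f)
    written <- f
    if (isTRUE(ecg)) {
      rec <- generate_ecg(series, ecg_template())
      base <- file.path(out_dir, "ecg")
      write_ecg(rec, base, format = "wfdb")
      written <- c(written, paste0(base, c(".hea", ".dat", ".atr")))
    }
    pf <- file.path(out_dir, "profile_manifest.csv")
    utils::write.csv(data.frame(mean_rr = profile$mean_rr, sdnn = profile$sdnn,
                                rsa_amp = profile$rsa_amp,
                                rsa_freq = profile$rsa_freq,
                                trend = profile$trend, n_beats = profile$n_beats,
                                seed = profile$seed),
                     pf, row.names = FALSE, quote = FALSE)
    written <- c(written, pf)
  }
  invisible(written)
}
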
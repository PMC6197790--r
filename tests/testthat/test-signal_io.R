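test_that("csv ECG round trip preserves samples, fs and t0", {
  rec <- ecg_record(c(0.1, 0.2, 0.1), fs = 256)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ecg(rec, f, "csv")
  back <- read_ecg(f, "csv")
  expect_equal(back$fs, 256)
  expect_equal(back$samples, rec$samples)
  expect_equal(back$t0, 0)
  expect_equal(length(readLines(f)), 4L)  # header + 3 data rows

  set.seed(11)
  rec2 <- ecg_record(rnorm(1000), fs = 200, t0 = 3.5)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_ecg(rec2, f2, "csv")
  back2 <- read_ecg(f2, "csv")
  expect_equal(back2$fs, 200)
  expect_equal(back2$t0, 3.5, tolerance = 1e-8)
  expect_equal(back2$samples, rec2$samples, tolerance = 1e-7)
})

test_that("csv ECG with non-uniform time grid is rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,amplitude",
               sprintf("%.9f,0.1", c(0, 1 / 256, 1 / 256 + 1 / 200))), f)
  expect_error(read_ecg(f, "csv"), "jitter", class = "riskplot_format_error")
  expect_error(read_ecg(file.path(tempdir(), "nope.csv"), "csv"),
               class = "riskplot_io_error")
})

test_that("wfdb round trip preserves samples to quantisation, fs and peaks", {
  set.seed(5)
  rec <- ecg_record(rnorm(2000, sd = 0.5), fs = 256,
                    truth_peaks = c(10L, 300L, 1500L, 1999L))
  base <- file.path(withr::local_tempdir(), "rec01")
  write_ecg(rec, base, "wfdb")
  expect_true(all(file.exists(paste0(base, c(".hea", ".dat", ".atr")))))
  back <- read_ecg(base, "wfdb")
  expect_equal(back$fs, 256)
  # format 16 at gain 2000/mV quantises to 0.0005 mV
  expect_lt(max(abs(back$samples - rec$samples)), 0.000251)
  expect_identical(back$truth_peaks, rec$truth_peaks)
})

test_that("wfdb write/read/write is byte-identical", {
  set.seed(6)
  rec <- ecg_record(rnorm(512), fs = 250, truth_peaks = c(5L, 100L, 400L))
  d <- withr::local_tempdir()
  write_ecg(rec, file.path(d, "a"), "wfdb")
  write_ecg(read_ecg(file.path(d, "a"), "wfdb"), file.path(d, "b"), "wfdb")
  for (ext in c(".dat", ".atr"))
    expect_identical(readBin(file.path(d, paste0("a", ext)), "raw", 1e5),
                     readBin(file.path(d, paste0("b", ext)), "raw", 1e5))
})

test_that("rri text round trip and beat-time reconstruction", {
  f <- withr::local_tempfile(fileext = ".rri")
  writeLines(c("# comment", "0.8", "0.8", "", "0.8"), f)
  s <- read_rri(f)
  expect_equal(s$intervals, rep(0.8, 3))
  expect_equal(s$beat_times, c(0, 0.8, 1.6, 2.4))

  set.seed(7)
  s2 <- rri_series(runif(1000, 0.3, 1.5))
  f2 <- withr::local_tempfile(fileext = ".rri")
  write_rri(s2, f2)
  back <- read_rri(f2)
  expect_lt(max(abs(back$intervals - s2$intervals)), 1e-6)
  expect_true(all(diff(back$beat_times) > 0))
  expect_equal(back$beat_times[length(back$beat_times)], sum(back$intervals),
               tolerance = 1e-9)
})

test_that("invalid rri files name the offending line", {
  f <- withr::local_tempfile(fileext = ".rri")
  writeLines("-0.1", f)
  expect_error(read_rri(f), "line 1", class = "riskplot_format_error")
  f2 <- withr::local_tempfile(fileext = ".rri")
  writeLines(c("0.8", "abc", "0.9"), f2)
  expect_error(read_rri(f2), "line 2", class = "riskplot_format_error")
})

test_that("container validity rules are enforced", {
  expect_error(ecg_record(c(1, NA), fs = 100), class = "riskplot_input_error")
  expect_error(ecg_record(1:10, fs = -1), class = "riskplot_input_error")
  expect_error(ecg_record(1:10, fs = 100, truth_peaks = c(3, 3)),
               class = "riskplot_input_error")
  expect_error(ecg_record(1:10, fs = 100, truth_peaks = 11),
               class = "riskplot_input_error")
  expect_error(rri_series(c(0.8, 0)), class = "riskplot_input_error")
  expect_error(peak_annotation(c(5, 2), 100), class = "riskplot_input_error")
})
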
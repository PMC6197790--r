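test_that("noiseless profile generates exactly constant intervals", {
  s <- generate_rri(synth_profile(mean_rr = 0.8, sdnn = 0, rsa_amp = 0,
                                  n_beats = 10, seed = 1))
  expect_equal(s$intervals, rep(0.8, 10))
  expect_equal(s$beat_times, seq(0, 8, by = 0.8))
})

test_that("generation is bit-reproducible and respects the 0.25 s floor", {
  p <- synth_profile(mean_rr = 0.5, sdnn = 0.3, n_beats = 500, seed = 42)
  a <- generate_rri(p)
  b <- generate_rri(p)
  expect_identical(a$intervals, b$intervals)
  expect_true(all(a$intervals >= 0.25))
  # a different seed gives a different stream
  expect_false(identical(
    generate_rri(synth_profile(seed = 43, n_beats = 100))$intervals,
    generate_rri(synth_profile(seed = 44, n_beats = 100))$intervals))
})

test_that("realized SDNN matches the profile at large n", {
  s <- generate_rri(synth_profile(mean_rr = 0.8, sdnn = 0.050, rsa_amp = 0,
                                  n_beats = 10000, seed = 3))
  expect_equal(sd(s$intervals), 0.050, tolerance = 0.05)  # within 5%
  expect_equal(mean(s$intervals), 0.8, tolerance = 0.01)
})

test_that("negative trend collapses variability over the record", {
  p <- synth_profile(mean_rr = 0.8, sdnn = 0.05, rsa_amp = 0,
                     trend = -0.04, n_beats = 4000, seed = 8)
  s <- generate_rri(p)
  first <- sd(s$intervals[1:500])
  last <- sd(s$intervals[3501:4000])
  expect_lt(last, first / 2)
})

test_that("rendered ECG has the right length and exact truth peaks", {
  s <- rri_series(rep(1.0, 3))
  rec <- generate_ecg(s, ecg_template(fs = 256))
  expect_length(rec$samples, 768L)
  expect_length(rec$truth_peaks, 3L)
  # R-wave centres at 0.25 s into each 1 s beat
  expect_equal(rec$truth_peaks, round((c(0, 1, 2) + 0.25) * 256) + 1L)
  # the R sample is the beat's maximum
  expect_equal(which.max(rec$samples[1:256]), rec$truth_peaks[1])
})

test_that("mains injection is visible before the notch and gone after", {
  s <- rri_series(rep(0.8, 25))
  rec <- generate_ecg(s, ecg_template(mains_amp = 0.3, mains_freq = 50))
  amp_before <- tone_amplitude(rec$samples, rec$fs, 50)
  expect_equal(amp_before, 0.3, tolerance = 0.05)
  filt <- notch_filter(rec)
  amp_after <- tone_amplitude(filt$samples, rec$fs, 50)
  expect_lt(20 * log10(amp_after / amp_before), -40)
})

test_that("clean rendering is recovered perfectly by the detector", {
  s <- generate_rri(synth_profile(mean_rr = 0.9, sdnn = 0.06, n_beats = 50,
                                  seed = 12))
  rec <- generate_ecg(s, ecg_template())
  pk <- detect_r_peaks(rec)
  expect_length(pk$indices, length(rec$truth_peaks))
  expect_lte(max(abs(pk$indices - rec$truth_peaks)), 2)
})

test_that("cohort generation is labelled, reproducible and separated in SDNN", {
  ch <- generate_cohort(6, 6, seed = 7, n_beats = 600)
  expect_length(ch$series, 12L)
  expect_equal(table(ch$manifest$label)[["healthy"]], 6L)
  expect_equal(table(ch$manifest$label)[["risk"]], 6L)
  ch2 <- generate_cohort(6, 6, seed = 7, n_beats = 600)
  expect_identical(lapply(ch$series, `[[`, "intervals"),
                   lapply(ch2$series, `[[`, "intervals"))
  realized <- vapply(ch$series, function(s) sd(s$intervals), numeric(1))
  healthy <- realized[ch$manifest$label == "healthy"]
  risk <- realized[ch$manifest$label == "risk"]
  expect_gt(min(healthy), max(risk))
  # every generated series passes its own invariants
  for (s in ch$series) expect_true(all(s$intervals >= 0.25))
})

test_that("invalid profiles are rejected", {
  expect_error(synth_profile(mean_rr = 0), class = "riskplot_config_error")
  expect_error(synth_profile(sdnn = -0.01), class = "riskplot_config_error")
  expect_error(synth_profile(n_beats = 0), class = "riskplot_config_error")
  expect_error(ecg_template(widths = c(P = 0.02, Q = 0.01, R = -0.01,
                                       S = 0.01, T = 0.04)),
               class = "riskplot_config_error")
})
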
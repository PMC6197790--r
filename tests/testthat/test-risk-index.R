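test_that("concentration spans 0 (uniform) to 1 (single stair)", {
  cfg <- rp_config(stair_edges = seq(0.3, 1.5, 0.1), drain_rate = 1,
                   capacity = 10, window_beats = 100)
  # all beats on one stair
  tr1 <- run_risk_plot(rri_series(rep(0.85, 100)), config = cfg)
  r1 <- window_index(tr1, 1)
  expect_equal(r1$concentration, 1)

  # beats uniform over all 12 stairs
  mids <- seq(0.35, 1.45, by = 0.1)
  tr0 <- run_risk_plot(rri_series(rep(mids, length.out = 96)),
                       config = rp_config(stair_edges = seq(0.3, 1.5, 0.1),
                                          window_beats = 96))
  r0 <- window_index(tr0, 1)
  expect_equal(r0$concentration, 0, tolerance = 1e-12)
})

test_that("constant-RRI window under per-beat drainage: only concentration fires", {
  cfg <- rp_config(stair_edges = seq(0.3, 1.5, 0.1), drain_rate = 1,
                   capacity = 8, window_beats = 100)
  tr <- run_risk_plot(rri_series(rep(0.8, 100)), config = cfg)
  r <- window_index(tr, 1)
  expect_equal(r$stuck_fraction, 0)
  expect_equal(r$throughput, 1)
  expect_equal(r$risk, 0.4 * 1)  # alpha * concentration
  expect_equal(r$alarm, "red")   # total concentration is the worst case
})

test_that("risk is invariant under stair relabelling fed equal counts", {
  # two streams whose count vectors are permutations of each other
  cfg <- rp_config(stair_edges = seq(0.3, 1.5, 0.1), window_beats = 60)
  a <- c(rep(0.35, 30), rep(0.65, 20), rep(1.25, 10))
  b <- c(rep(1.25, 30), rep(0.35, 20), rep(0.65, 10))
  ra <- window_index(run_risk_plot(rri_series(a), config = cfg), 1)
  rb <- window_index(run_risk_plot(rri_series(b), config = cfg), 1)
  expect_equal(ra$risk, rb$risk)
  expect_equal(ra$concentration, rb$concentration)
})

test_that("components stay in [0,1] across random traces", {
  set.seed(404)
  for (rep in 1:10) {
    case <- random_rp_case(1200)
    tr <- run_risk_plot(case$series, case$mask, case$config)
    rs <- risk_series(tr)
    for (col in c("concentration", "stuck_fraction", "throughput", "risk")) {
      expect_true(all(rs[[col]] >= 0 & rs[[col]] <= 1))
    }
  }
})

test_that("healthy and near-death profiles separate into green and red alarms", {
  healthy <- generate_rri(synth_profile(mean_rr = 0.8, sdnn = 0.050,
                                        rsa_amp = 0.025, n_beats = 1550,
                                        seed = 1))
  trh <- run_risk_plot(healthy, quality_mask(healthy))
  rh <- risk_series(trh, include_partial = FALSE)
  expect_true(all(rh$alarm == "green"))

  neardeath <- generate_rri(synth_profile(mean_rr = 0.8, sdnn = 0.005,
                                          rsa_amp = 0.002, n_beats = 1550,
                                          seed = 1))
  trn <- run_risk_plot(neardeath, quality_mask(neardeath))
  rn <- risk_series(trn, include_partial = FALSE)
  expect_true(all(rn$alarm == "red"))
  expect_gt(min(rn$risk), max(rh$risk))

  # determinism: same input, same config, same output
  rn2 <- risk_series(run_risk_plot(neardeath, quality_mask(neardeath)),
                     include_partial = FALSE)
  expect_identical(rn, rn2)
})

test_that("risk_series errors without a complete window; partials are labelled", {
  s <- rri_series(rep(0.8, 50))
  tr <- run_risk_plot(s, config = rp_config(window_beats = 300))
  expect_error(risk_series(tr), "complete window",
               class = "riskplot_input_error")
  tr2 <- run_risk_plot(rri_series(rep(0.8, 350)),
                       config = rp_config(window_beats = 300))
  rs <- risk_series(tr2)
  expect_identical(rs$partial, c(FALSE, TRUE))
  rs_complete <- risk_series(tr2, include_partial = FALSE)
  expect_equal(nrow(rs_complete), 1L)
})

test_that("dispersion_summary computes per-window SDNN", {
  expect_equal(dispersion_summary(rri_series(rep(0.8, 3)), 10)$sdnn, 0)
  expect_equal(dispersion_summary(rri_series(c(0.7, 0.9)), 10)$sdnn,
               sd(c(0.7, 0.9)), tolerance = 1e-12)
  expect_equal(dispersion_summary(rri_series(c(0.7, 0.9)), 10)$sdnn, 0.1414,
               tolerance = 1e-3)

  s <- generate_rri(synth_profile(mean_rr = 0.8, sdnn = 0.050, rsa_amp = 0,
                                  n_beats = 10000, seed = 6))
  ds <- dispersion_summary(s, 10000)
  expect_equal(ds$sdnn, 0.050, tolerance = 0.05)  # within 5%
  expect_error(dispersion_summary(rri_series(0.8), 10),
               class = "riskplot_input_error")
})

test_that("weights and thresholds are validated", {
  expect_error(risk_weights(0.5, 0.5, 0.5), class = "riskplot_config_error")
  expect_error(alarm_thresholds(0.7, 0.5), class = "riskplot_config_error")
  expect_silent(risk_weights(1, 0, 0))
})
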
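# Stair indices are 1-based throughout (bin k covers [e_k, e_{k+1})).

coarse_cfg <- function(...) {
  rp_config(stair_edges = seq(0.3, 1.5, by = 0.1), ...)
}

test_that("assign_stair bins half-open with a closed right edge", {
  cfg <- coarse_cfg()
  expect_identical(assign_stair(0.80, cfg), 6L)   # floor((0.8 - 0.3)/0.1) + 1
  expect_identical(assign_stair(0.30, cfg), 1L)
  expect_identical(assign_stair(0.3999, cfg), 1L)
  expect_identical(assign_stair(0.40, cfg), 2L)
  expect_identical(assign_stair(1.50, cfg), 12L)  # right edge closed
  expect_identical(assign_stair(2.0, cfg), 12L)   # clamp
  expect_identical(assign_stair(0.1, cfg), 1L)
  drop_cfg <- coarse_cfg(oor_policy = "drop")
  expect_identical(assign_stair(2.0, drop_cfg), NA_integer_)
  expect_identical(assign_stair(1.50, drop_cfg), 12L)
  expect_error(assign_stair(-0.5, cfg), class = "riskplot_input_error")
})

test_that("project_beat and drain_step implement the token rules", {
  cfg <- coarse_cfg(drain_rate = 2, capacity = 8)
  st <- rp_state(cfg)
  st <- project_beat(st, 0.85, cfg)
  expect_equal(st$occupancy[6], 1L)
  expect_equal(st$projected, 1L)
  expect_equal(st$valley, 0L)
  expect_identical(occupancy_histogram(st), st$occupancy)
  expect_equal(sum(occupancy_histogram(st)),
               st$projected - st$valley - st$dropped)

  # reaching capacity via projection sets the stuck flag
  st2 <- rp_state(cfg)
  st2$occupancy[6] <- 7L
  st2 <- project_beat(st2, 0.85, cfg)
  expect_true(st2$stuck[6])

  # out-of-range drop is counted, occupancy untouched
  dcfg <- coarse_cfg(oor_policy = "drop")
  st3 <- project_beat(rp_state(dcfg), 2.5, dcfg)
  expect_equal(st3$projected, 1L)
  expect_equal(st3$dropped, 1L)
  expect_equal(sum(st3$occupancy), 0L)

  # drain: min rule, stuck stairs drain nothing
  st4 <- rp_state(cfg)
  st4$occupancy <- c(3L, rep(0L, 11))
  st4 <- drain_step(st4, cfg)
  expect_equal(st4$occupancy[1], 1L)
  expect_equal(st4$valley, 2L)

  st5 <- rp_state(cfg)
  st5$occupancy <- c(9L, rep(0L, 11))
  st5$stuck <- st5$occupancy >= cfg$capacity
  st5 <- drain_step(st5, cfg)
  expect_equal(st5$occupancy[1], 9L)
  expect_equal(st5$valley, 0L)

  st6 <- rp_state(cfg)
  st6$occupancy <- c(1L, 1L, rep(0L, 10))
  st6 <- drain_step(st6, cfg)
  expect_equal(sum(st6$occupancy), 0L)
  expect_equal(st6$valley, 2L)
})

test_that("hand-worked dynamics: drain keeps pace with identical intervals", {
  cfg <- coarse_cfg(drain_rate = 1, capacity = 10, window_beats = 100)
  tr <- run_risk_plot(rri_series(rep(0.8, 3)), config = cfg)
  expect_equal(sum(tr$occupancy[1, ]), 0L)
  expect_equal(tr$windows$valley, 3)
  expect_equal(tr$windows$projected, 3)
})

test_that("hand-worked dynamics: with no drainage the stair sticks at beat 8", {
  cfg <- coarse_cfg(drain_rate = 0, capacity = 8, window_beats = 100)
  tr <- run_risk_plot(rri_series(rep(0.8, 100)), config = cfg,
                      record = "beats")
  target <- assign_stair(0.8, cfg)
  first_stuck <- which(tr$beats$log$any_stuck)[1]
  expect_equal(tr$beats$log$beat[first_stuck], 8)
  expect_true(all(tr$beats$log$any_stuck[first_stuck:nrow(tr$beats$log)]))
  expect_equal(tr$occupancy[1, target], 100L)
  expect_equal(tr$windows$valley, 0)
})

test_that("conservation holds after every event on a random stream", {
  set.seed(101)
  case <- random_rp_case(5000)
  tr <- run_risk_plot(case$series, case$mask, case$config, record = "events")
  log <- tr$beats$log
  expect_true(all(log$projected ==
                  rowSums(tr$beats$occupancy) + log$valley + log$dropped))
  expect_true(all(tr$beats$occupancy >= 0L))
  # valley is non-decreasing within each window
  for (w in unique(log$window))
    expect_true(all(diff(log$valley[log$window == w]) >= 0))
})

test_that("production engine reproduces the naive reference simulator exactly", {
  set.seed(202)
  for (rep in 1:25) {
    case <- random_rp_case(400)
    pr <- run_risk_plot(case$series, case$mask, case$config, record = "events")
    rf <- rp_reference(case$series, case$mask, case$config)
    expect_true(all(unname(as.matrix(pr$beats$occupancy)) == rf$event_occupancy))
    expect_true(all(pr$beats$log$valley == rf$events$valley))
    expect_true(all(pr$beats$log$projected == rf$events$projected))
    expect_true(all(pr$beats$log$dropped == rf$events$dropped))
    expect_identical(pr$beats$log$stair, rf$events$stair)
    expect_identical(pr$beats$log$any_stuck, rf$events$any_stuck)
    expect_true(all(unname(as.matrix(pr$occupancy)) == rf$terminal_occupancy))
  }
})

test_that("flagged beats are skipped and do not advance the window clock", {
  s <- rri_series(rep(0.8, 10))
  mask <- rep(c(FALSE, TRUE), 5)
  cfg <- coarse_cfg(window_beats = 5)
  tr <- run_risk_plot(s, mask, cfg)
  expect_equal(nrow(tr$windows), 1L)
  expect_false(tr$windows$partial[1])
  expect_equal(tr$windows$n_beats, 5)
  expect_equal(tr$windows$projected, 5)
  expect_error(run_risk_plot(s, rep(TRUE, 10), cfg),
               class = "riskplot_input_error")
})

test_that("stationarity: constant stream with d >= 1 leaves the stair empty after each beat", {
  cfg <- coarse_cfg(drain_rate = 1, capacity = 8, window_beats = 1000)
  tr <- run_risk_plot(rri_series(rep(0.73, 200)), config = cfg,
                      record = "beats")
  expect_true(all(tr$beats$occupancy == 0L))
  expect_equal(tr$windows$valley, 200)
})

test_that("increasing the drain rate never increases terminal occupancy", {
  set.seed(77)
  x <- rri_series(runif(2000, 0.3, 1.5))
  totals <- sapply(0:4, function(d) {
    cfg <- coarse_cfg(drain_rate = d, capacity = 9, window_beats = 250)
    tr <- run_risk_plot(x, config = cfg)
    rowSums(tr$occupancy)
  })
  expect_true(all(apply(totals, 1, diff) <= 0))
})

test_that("window resets partition the stream and partial windows are flagged", {
  set.seed(13)
  s <- rri_series(runif(730, 0.3, 1.5))
  cfg <- coarse_cfg(window_beats = 300)
  tr <- run_risk_plot(s, config = cfg)
  expect_equal(tr$windows$window, 1:3)
  expect_equal(tr$windows$n_beats, c(300, 300, 130))
  expect_identical(tr$windows$partial, c(FALSE, FALSE, TRUE))
  expect_equal(sum(tr$windows$projected), 730)
  # per-window conservation at the terminal snapshot
  expect_true(all(tr$windows$projected ==
                  rowSums(tr$occupancy) + tr$windows$valley + tr$windows$dropped))
})

test_that("rp_config rejects invalid geometry and rates", {
  expect_error(rp_config(stair_edges = c(0.3, 0.3, 0.5)),
               class = "riskplot_config_error")
  expect_error(rp_config(stair_edges = c(0.3, 0.5)),
               class = "riskplot_config_error")
  expect_error(rp_config(drain_rate = 2, capacity = 2),
               class = "riskplot_config_error")
  expect_error(rp_config(drain_rate = -1), class = "riskplot_config_error")
  expect_error(rp_config(window_beats = 0), class = "riskplot_config_error")
})
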
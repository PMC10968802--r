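test_that("live_gate retains exactly the events passing the scatter thresholds", {
  ev <- data.frame(fsc = 1:5, ssc = c(10, 10, 10, 10, 99),
                   cd24 = 1, cd44 = 1, aldh1 = 1, abcg2 = 1)
  expect_identical(live_gate(ev, gate_spec(fsc_min = 0)), ev)
  expect_equal(nrow(live_gate(ev, gate_spec(fsc_min = 3))), 3L)
  expect_equal(nrow(live_gate(ev, gate_spec(fsc_min = 3, ssc_max = 50))), 2L)
  # order preserved
  expect_equal(live_gate(ev, gate_spec(fsc_min = 3))$fsc, c(3, 4, 5))
  expect_warning(live_gate(ev, gate_spec(fsc_min = 100)), "zero events")
  expect_error(live_gate(data.frame(x = 1), gate_spec(fsc_min = 1)), "fsc")
})

test_that("live_gate is idempotent and monotone in fsc_min", {
  cfg <- cytosim_config(n_events = 3000, seed = 6)
  ev <- simulate_events(cfg)
  g <- default_gate(cfg)
  once <- live_gate(ev, g)
  expect_identical(live_gate(once, g), once)
  counts <- vapply(c(0, 1e3, 1e4, 2e4, 5e4),
                   function(m) nrow(suppressWarnings(
                     live_gate(ev, gate_spec(fsc_min = m)))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("percent_positive counts signature-matching live events", {
  ev <- make_events(n = 1000, n_match = 175)
  g <- basic_gate()
  expect_equal(percent_positive(ev, "CD44+", g), 17.5)
  # threshold below every intensity: all positive
  g_low <- gate_spec(fsc_min = 0, thresholds = c(cd44 = 0.5))
  expect_equal(percent_positive(ev, "CD44+", g_low), 100)
  # debris outside the live gate never enters the quadrant statistic
  ev2 <- make_events(n = 1000, n_match = 175, n_debris = 500)
  expect_equal(percent_positive(ev2, "CD44+", g), 17.5)
  # events exactly at the threshold count as positive
  ev3 <- data.frame(fsc = 100, ssc = 1, cd24 = 1, cd44 = 10, aldh1 = 1, abcg2 = 1)
  expect_equal(percent_positive(ev3, "CD44+", g), 100)
  expect_error(percent_positive(ev3, "CD44+", gate_spec(fsc_min = 1e9,
    thresholds = c(cd44 = 10))), "empty live gate")
})

test_that("signature percentages over all marker-state combinations sum to 100", {
  cfg <- cytosim_config(n_events = 10000, seed = 13)
  ev <- simulate_events(cfg)
  g <- default_gate(cfg)
  combos <- expand.grid(cd24 = c("positive", "negative"),
                        cd44 = c("positive", "negative"),
                        aldh1 = c("positive", "negative"),
                        abcg2 = c("positive", "negative"),
                        stringsAsFactors = FALSE)
  total <- sum(vapply(seq_len(nrow(combos)), function(i) {
    percent_positive(ev, signature_query(as.list(combos[i, ])), g)
  }, numeric(1)))
  expect_equal(total, 100)
})

test_that("gating recovers simulator ground truth with well-separated clusters", {
  q <- signature_query("CD24-,CD44+")
  cfg <- cytosim_config(n_events = 1e5, joint_probs = signature_joint(q, 0.05),
                        seed = 17)
  ev <- simulate_events(cfg)
  g <- default_gate(cfg)
  # live gate agrees with ground truth labels (<= 0.5% disagreement)
  kept <- ev$fsc >= g$fsc_min
  expect_lt(mean(kept != ev$truth_live), 0.005)
  # percent positive within 0.5 percentage points of the configured 5%
  expect_lt(abs(percent_positive(ev, q, g) - 5.0), 0.5)
})

test_that("series_from_events assembles sorted series and rejects duplicates", {
  g <- basic_gate()
  tabs <- list(
    list(time_h = 33, replicate = 1, events = make_events(200, 50)),
    list(time_h = 24, replicate = 1, events = make_events(200, 20)),
    list(time_h = 24, replicate = 2, events = make_events(200, 30))
  )
  s <- series_from_events(tabs, "CD44+", g, cell_line = "HCT-116",
                          signature = "CD44+", treatment = "treated")
  expect_equal(nrow(s), 3L)
  expect_equal(s$time_h, c(24, 24, 33))
  expect_equal(s$percent, c(10, 15, 25))
  # permuted input gives the identical sorted series
  s2 <- series_from_events(tabs[c(3, 1, 2)], "CD44+", g, cell_line = "HCT-116",
                           signature = "CD44+", treatment = "treated")
  expect_identical(s, s2)
  tabs_dup <- tabs[c(1, 1)]
  expect_error(series_from_events(tabs_dup, "CD44+", g), "duplicate")
})

test_that("the signature mini-language parses labels and rejects nonsense", {
  q <- signature_query("CD24-,CD44+")
  expect_equal(q$cd24, "negative")
  expect_equal(q$cd44, "positive")
  expect_equal(q$aldh1, "ignored")
  # compact label form used in figure captions
  q2 <- signature_query("CD44+ABCG2+ALDH1+")
  expect_equal(q2$cd44, "positive")
  expect_equal(q2$abcg2, "positive")
  expect_equal(q2$aldh1, "positive")
  expect_equal(q2$cd24, "ignored")
  expect_error(signature_query("XYZ+"), "unknown marker")
  expect_error(signature_query(list(cd44 = "maybe")), "positive/negative/ignored")
})
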
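test_that("csc_fraction matches the closed form of the two-compartment model", {
  # equal kill rates leave the fraction unchanged
  p_eq <- selection_params(f0 = 0.05, d_r = 0.01, d_s = 0.01)
  expect_equal(csc_fraction(p_eq, 100, treated = TRUE), 0.05)
  # initial condition
  p <- selection_params(f0 = 0.05, d_r = 0.002, d_s = 0.002 + 0.0268)
  expect_equal(csc_fraction(p, 0, treated = TRUE), 0.05)
  # hand-evaluated closed form: e^(0.0268*52) = e^1.3936 ~ 4.030
  expect_equal(csc_fraction(p, 52, treated = TRUE), 0.1750, tolerance = 0.0005 / 0.1750)
  # control arm is time-invariant
  expect_equal(csc_fraction(p, c(0, 24, 52, 500), treated = FALSE),
               rep(0.05, 4))
  expect_error(csc_fraction(p, -1), "non-negative")
})

test_that("fold_enrichment reproduces the 3.5-fold treated/control ratio at 52 h", {
  p <- selection_params(f0 = 0.05, d_r = 0.002, d_s = 0.002 + 0.0268)
  expect_equal(fold_enrichment(p, 0), 1.0)
  expect_equal(fold_enrichment(p, 52), 3.50, tolerance = 0.01 / 3.5)
  p_eq <- selection_params(d_r = 0.01, d_s = 0.01)
  expect_equal(fold_enrichment(p_eq, 77), 1.0)
})

test_that("fold_enrichment depends only on the rate difference d_s - d_r", {
  for (shift in c(0, 0.001, 0.01, 0.05)) {
    p <- selection_params(f0 = 0.05, d_r = 0.002 + shift, d_s = 0.0288 + shift)
    expect_equal(fold_enrichment(p, 52), 3.4993, tolerance = 1e-4)
  }
})

test_that("dead_fraction follows the survival model and dominates the control arm", {
  p <- selection_params(f0 = 0.05, d_r = 0.002, d_s = 0.0288, d0 = 0.001)
  expect_equal(dead_fraction(p, 0, treated = TRUE), 0)
  expect_equal(dead_fraction(p, 0, treated = FALSE), 0)
  # hand evaluation: 1 - (0.05 e^-0.048 + 0.95 e^-0.6912)
  expect_equal(dead_fraction(p, 24, treated = TRUE), 0.4764, tolerance = 0.001 / 0.4764)
  p0 <- selection_params(d0 = 0)
  expect_equal(dead_fraction(p0, c(10, 100), treated = FALSE), c(0, 0))
  # treated >= control whenever d_s >= d_r >= d0, and both non-decreasing
  tt <- seq(0, 100, by = 5)
  expect_true(all(diff(dead_fraction(p, tt, TRUE)) >= 0))
  expect_true(all(diff(dead_fraction(p, tt, FALSE)) >= 0))
  expect_true(all(dead_fraction(p, tt, TRUE) >= dead_fraction(p, tt, FALSE)))
})

test_that("treated csc_fraction is non-decreasing and bounded on random parameter draws", {
  set.seed(7)
  tt <- seq(0, 120, by = 8)
  for (i in 1:1000) {
    f0 <- runif(1, 0.01, 0.6)
    d_r <- runif(1, 0, 0.01)
    d_s <- d_r + runif(1, 1e-4, 0.05)
    p <- selection_params(f0 = f0, d_r = d_r, d_s = d_s)
    fr <- csc_fraction(p, tt, treated = TRUE)
    expect_true(all(diff(fr) >= 0))
    expect_true(all(fr >= f0 - 1e-12 & fr < 1))
  }
})

test_that("generate_series is deterministic and unbiased around the closed form", {
  p0 <- selection_params(noise_sd = 0)
  pair <- generate_series(p0, "HCT-116", "CD44+ABCG2+ALDH1+", seed = 5)
  truth <- 100 * csc_fraction(p0, pair$treated$time_h, treated = TRUE)
  expect_equal(pair$treated$percent, truth)
  expect_equal(pair$control$percent, rep(100 * p0$f0, nrow(pair$control)))

  p <- selection_params()
  a <- generate_series(p, "HCT-116", "CD44+", seed = 11)
  b <- generate_series(p, "HCT-116", "CD44+", seed = 11)
  expect_identical(a, b)
  c2 <- generate_series(p, "HCT-116", "CD44+", seed = 12)
  expect_false(identical(a$treated$percent, c2$treated$percent))

  # Monte-Carlo: with 1000 replicates the per-time mean sits within 3 SE
  pm <- selection_params(noise_sd = 1, n_replicates = 1000)
  big <- generate_series(pm, "x", "y", seed = 1)$treated
  se <- 1 / sqrt(1000)
  for (tt in pm$times) {
    mu <- 100 * csc_fraction(pm, tt, TRUE)
    expect_lt(abs(mean(big$percent[big$time_h == tt]) - mu), 3 * se)
  }
})

test_that("noise-free series round-trip through the CSV format", {
  p0 <- selection_params(noise_sd = 0)
  pair <- generate_series(p0, "MDA-MB-231", "CD24-CD44+", seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_marker_series(pair$treated, path)
  back <- read_marker_series(path)
  expect_equal(back$percent, pair$treated$percent, tolerance = 1e-12)
  expect_equal(back$time_h, pair$treated$time_h)
  expect_equal(back$cell_line, pair$treated$cell_line)
})

test_that("selection_params rejects invalid inputs", {
  expect_error(selection_params(f0 = 0), "between 0 and 1")
  expect_error(selection_params(f0 = 1.2), "between 0 and 1")
  expect_error(selection_params(d_r = 0.05, d_s = 0.01), "d_s")
  expect_error(selection_params(times = c(30, 20)), "increasing")
  expect_error(selection_params(noise_sd = -1), "noise_sd")
})
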
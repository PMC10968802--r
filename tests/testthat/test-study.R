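test_that("simulate_study produces the 2 x 3 x 2 design deterministically", {
  cfg <- study_config()
  sim <- simulate_study(cfg)
  ids <- unique(sim$series[, c("cell_line", "signature", "treatment")])
  expect_equal(nrow(ids), 12L)
  expect_setequal(unique(ids$cell_line), c("MDA-MB-231", "HCT-116"))
  expect_true(all(sim$series$percent >= 0 & sim$series$percent <= 100))
  # same master seed reproduces the series exactly
  sim2 <- simulate_study(study_config())
  expect_identical(sim$series, sim2$series)
  # different master seed: same schema, different noise
  sim3 <- simulate_study(study_config(master_seed = 7))
  expect_identical(names(sim3$series), names(sim$series))
  expect_false(identical(sim3$series$percent, sim$series$percent))
})

test_that("simulate_study writes per-series files plus a checksum manifest", {
  dir1 <- withr::local_tempdir()
  sim <- simulate_study(study_config(), out_dir = dir1)
  expect_equal(nrow(sim$manifest), 12L)
  expect_true(all(file.exists(file.path(dir1, sim$manifest$file))))
  expect_true(file.exists(file.path(dir1, "manifest.csv")))
  expect_true(file.exists(file.path(dir1, "series.csv")))
  # a rerun with the same seed reproduces every checksum
  dir2 <- withr::local_tempdir()
  sim2 <- simulate_study(study_config(), out_dir = dir2)
  expect_identical(sim$manifest$md5, sim2$manifest$md5)
})

test_that("study_config reads YAML and accepts overrides", {
  cfg <- study_config()
  expect_equal(cfg$master_seed, 42L)
  expect_equal(cfg$selection$d_s - cfg$selection$d_r, 0.0268)
  expect_equal(cfg$gp$population_size, 1000L)
  cfg2 <- study_config(master_seed = 9)
  expect_equal(cfg2$master_seed, 9L)
  # user YAML overrides the packaged defaults
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("master_seed: 3", "selection:", "  noise_sd: 0.5"), path)
  cfg3 <- study_config(path)
  expect_equal(cfg3$master_seed, 3L)
  expect_equal(cfg3$selection$noise_sd, 0.5)
  expect_equal(cfg3$selection$d_r, 0.002)  # untouched default
})

test_that("end_to_end chains simulate, fit and compare on the fast path", {
  cfg <- study_config()
  cfg$gp$population_size <- 150L
  cfg$gp$max_generations <- 6L
  cfg$gp$tournament_size <- 5L
  out <- withr::local_tempdir()
  res <- end_to_end(cfg, out_dir = out, quiet = TRUE)
  expect_equal(nrow(res$results), 12L)
  expect_named(res$summary, c("mean_r2", "min_r2", "max_r2"))
  expect_equal(nrow(res$stats), 6 * length(cfg$selection$times))
  expect_true(all(file.exists(file.path(out,
    c("results.csv", "stats.csv", "summary.txt", "manifest.csv")))))
  # treated vs control separation is detected for the strong signatures
  strong <- res$stats[res$stats$time_h == 52 &
                        res$stats$signature == "CD44+ABCG2+ALDH1+", ]
  expect_lt(strong$p_value, 0.05)
})

test_that("the event-level path reproduces the survival-model percentages", {
  cfg <- study_config()
  cfg$gp$population_size <- 150L
  cfg$gp$max_generations <- 4L
  cfg$gp$tournament_size <- 5L
  cfg$cytosim$n_events <- 5000L
  cfg$selection$times <- c(24, 33, 43, 52)
  res <- end_to_end(cfg, skip_events = FALSE, quiet = TRUE)
  sim <- simulate_study(cfg)
  # gated percentages track the model truth (binomial + gating error only)
  for (sig in c("CD44+", "ALDH1+")) {
    ev_pct <- res$series$percent[res$series$cell_line == "HCT-116" &
                                   res$series$signature == sig &
                                   res$series$treatment == "treated" &
                                   res$series$time_h == 52]
    p <- selection_params(f0 = cfg$study_design[["HCT-116"]][[sig]],
                          d_r = cfg$selection$d_r, d_s = cfg$selection$d_s)
    truth <- 100 * csc_fraction(p, 52, treated = TRUE)
    expect_lt(abs(mean(ev_pct) - truth), 3)
  }
})
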
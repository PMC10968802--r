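# Small, fast GP configuration for unit tests (acceptance tests use the
# full-size defaults).
quick_gp <- function(seed = 1L, ...) {
  gp_config(population_size = 150L, max_generations = 8L,
            tournament_size = 5L, seed = seed, ...)
}

# Build a marker series directly from a truth function of time.
make_series <- function(truth, times = c(24, 33, 43, 52), n_rep = 3,
                        noise_sd = 0, seed = 1L,
                        cell_line = "HCT-116", signature = "CD44+",
                        treatment = "treated") {
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(n_rep), time_h = times)
  pct <- truth(grid$time_h) + rnorm(nrow(grid), 0, noise_sd)
  structure(data.frame(cell_line = cell_line, signature = signature,
                       treatment = treatment, time_h = grid$time_h,
                       replicate = grid$replicate,
                       percent = pmin(pmax(pct, 0), 100),
                       stringsAsFactors = FALSE),
            class = c("marker_series", "data.frame"))
}

# Event table with known composition: `n_match` of `n` live events satisfy
# CD44+ at threshold 10 (others at intensity 1), plus `n_debris` low-FSC.
make_events <- function(n = 1000, n_match = 175, n_debris = 0) {
  n_rest <- n - n_match
  data.frame(
    fsc = c(rep(100, n), rep(1, n_debris)),
    ssc = rep(50, n + n_debris),
    cd24 = rep(1, n + n_debris),
    cd44 = c(rep(20, n_match), rep(1, n_rest), rep(20, n_debris)),
    aldh1 = rep(1, n + n_debris),
    abcg2 = rep(1, n + n_debris)
  )
}

basic_gate <- function() {
  gate_spec(fsc_min = 10,
            thresholds = c(cd24 = 10, cd44 = 10, aldh1 = 10, abcg2 = 10))
}
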
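test_that("fitness is RMSE plus a parsimony penalty on node count", {
  xs <- c(24, 33, 43)
  tr <- parse_tree("add(mult(0.5, t), 2)")
  f <- fitness(tr, xs, 0.5 * xs + 2, 0.01)
  expect_equal(f$raw_fitness, 0)
  expect_equal(f$node_count, 5L)
  expect_equal(f$penalized_fitness, 0.05)
  # constant trees against a constant target
  expect_equal(fitness(gp_const(10), 1:3, c(10, 10, 10), 0)$raw_fitness, 0)
  expect_equal(fitness(gp_const(13), 1:3, c(10, 10, 10), 0)$raw_fitness, 3)
  # formula application: raw 0.5, 7 nodes, coefficient 0.01
  tr7 <- parse_tree("add(add(t, 1), add(t, 2))")
  stopifnot(node_count(tr7) == 7)
  f2 <- fitness(tr7, 0, 0.5 + eval_tree(tr7, 0), 0.01)
  expect_equal(f2$penalized_fitness, 0.57)
  expect_error(fitness(tr, 1:3, 1:4), "equal length")
})

test_that("tournament selection prefers low penalized fitness with fair draws", {
  mk <- function(pen, nodes = 1) structure(
    list(tree = gp_var(), raw_fitness = pen, penalized_fitness = pen,
         node_count = nodes), class = "gp_individual")
  pop1 <- list(mk(0.4))
  expect_identical(tournament_select(pop1, 3), pop1[[1]])
  # two members {0.1, 0.9}, k = 2 draws with replacement: best wins 3/4
  pop2 <- list(mk(0.1), mk(0.9))
  set.seed(5)
  wins <- mean(replicate(4000,
    tournament_select(pop2, 2)$penalized_fitness == 0.1))
  expect_equal(wins, 0.75, tolerance = 0.03)
  # k = 1 is a uniform draw
  set.seed(6)
  share <- mean(replicate(4000,
    tournament_select(pop2, 1)$penalized_fitness == 0.1))
  expect_equal(share, 0.5, tolerance = 0.05)
  # equal fitness resolved by fewer nodes (k large enough to draw both)
  pop3 <- list(mk(0.2, nodes = 9), mk(0.2, nodes = 2))
  set.seed(8)
  expect_equal(tournament_select(pop3, 50)$node_count, 2)
  expect_error(tournament_select(list(), 2), "empty")
})

test_that("subtree crossover respects the depth cap and degenerate parents", {
  t_leaf <- gp_var()
  expect_identical(subtree_crossover(t_leaf, t_leaf), t_leaf)
  cfg <- gp_config()
  set.seed(3)
  for (k in 1:2000) {
    a <- random_tree("grow", c(2, 6), cfg)
    b <- random_tree("grow", c(2, 6), cfg)
    expect_lte(tree_depth(subtree_crossover(a, b, max_depth = 8)), 8)
  }
  set.seed(11); c1 <- subtree_crossover(random_tree("full", c(3, 3), cfg),
                                        random_tree("full", c(3, 3), cfg))
  set.seed(11); c2 <- subtree_crossover(random_tree("full", c(3, 3), cfg),
                                        random_tree("full", c(3, 3), cfg))
  expect_identical(c1, c2)
})

test_that("mutation kinds honour their structural contracts", {
  cfg <- gp_config()
  leaf <- gp_var()
  set.seed(1)
  expect_identical(mutate_tree(leaf, "hoist", cfg), leaf)
  set.seed(2)
  for (k in 1:1000) {
    tr <- random_tree("grow", c(1, 5), cfg)
    pm <- mutate_tree(tr, "point", cfg)
    expect_equal(length(pm$ops), length(tr$ops))   # shape preserved
    hm <- mutate_tree(tr, "hoist", cfg)
    expect_lte(node_count(hm), node_count(tr))
    sm <- mutate_tree(tr, "subtree", cfg)
    expect_lte(tree_depth(sm), cfg$max_depth)
  }
  expect_error(mutate_tree(leaf, "sideways", cfg), "arg")
})

test_that("evolve is deterministic, elitist, and stops as configured", {
  xs <- c(24, 33, 43, 52)
  ys <- c(9.1, 11.3, 14.3, 17.5)
  cfg <- quick_gp(seed = 77)
  f1 <- evolve(xs, ys, cfg)
  f2 <- evolve(xs, ys, cfg)
  expect_identical(serialize_tree(f1$best$tree), serialize_tree(f2$best$tree))
  expect_identical(f1$history, f2$history)
  # elitism: best penalized fitness never worsens across generations
  cfg2 <- quick_gp(seed = 5, stopping_threshold = 0)
  f3 <- evolve(xs, ys, cfg2)
  expect_true(all(diff(f3$history$best_penalized) <= 1e-12))
  # infinite stopping threshold: return after the initial generation
  f4 <- evolve(xs, ys, quick_gp(stopping_threshold = Inf))
  expect_equal(f4$generations, 1L)
  expect_equal(nrow(f4$history), 1L)
})

test_that("evolve recovers a planted line to machine precision", {
  xs <- c(24, 33, 43, 52, 60)
  ys <- 0.5 * xs + 2
  fit <- evolve(xs, ys, gp_config(population_size = 500,
                                  max_generations = 40, seed = 42))
  expect_lt(fit$best$raw_fitness, 1e-6)
  expect_lt(fit$generations, 40)
  # the reported expression reproduces the fit when re-evaluated
  expect_equal(eval_tree(fit$best$tree, xs), ys, tolerance = 1e-6)
})

test_that("time scaling is undone transparently in predictions", {
  xs <- c(24, 33, 43)
  ys <- c(10, 14, 20)
  fit <- evolve(xs, ys, quick_gp(seed = 3, scale_time = TRUE))
  expect_equal(fit$t_range, c(24, 43))
  expect_true(all(is.finite(gp_predict(fit, c(52, 67)))))
  expect_equal(gp_predict(fit, xs),
               eval_tree(fit$best$tree, (xs - 24) / 19))
})

test_that("gp_config validates hyperparameters", {
  expect_error(gp_config(p_crossover = 0.95, p_subtree_mutation = 0.1),
               "sum to <= 1")
  expect_error(gp_config(population_size = 1), "population_size")
  expect_error(gp_config(tournament_size = 5000), "tournament_size")
  expect_error(gp_config(init_depth_range = c(2, 20)), "init_depth_range")
  expect_error(gp_config(parsimony_coefficient = -1), "parsimony")
})
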
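test_that("fitness is the F-measure of the thresholded ensemble", {
  ctx <- perfect_context()
  expect_equal(ga_fitness(c(1, 0, 0), ctx), 1)
  expect_equal(ga_fitness(c(1, 0, 0), ctx), ga_fitness(c(1, 0, 0), ctx))
  # a weight vector predicting nothing scores zero
  empty_ctx <- ga_context(list(a = c(t = 0.1), b = c(t = 0.1),
                               c = c(t = 0.1)),
                          build_ground_truth(list("t"), c(t = "domain")))
  expect_equal(ga_fitness(c(1, 0, 0), empty_ctx), 0)
})

test_that("naive crossover reproduces the hand-computed children", {
  kids <- naive_crossover(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5))
  expect_equal(kids[[1]], c(10, 9, 10) / 29)
  expect_equal(kids[[2]], c(0.35, 0.30, 0.35))
  u <- rep(1 / 3, 3)
  kids2 <- naive_crossover(u, u)
  expect_equal(kids2[[1]], u)
  expect_equal(kids2[[2]], u)
})

test_that("domination crossover picks the largest and second largest weight", {
  kids <- domination_crossover(c(0.1, 0.2, 0.7), c(0.6, 0.3, 0.1))
  expect_equal(kids[[1]], c(0.15, 0.15, 0.7))
  expect_equal(kids[[2]], c(0.6, 0.2, 0.2))
  u <- rep(1 / 3, 3)
  kids2 <- domination_crossover(u, u)
  expect_equal(kids2[[1]], u)
  expect_equal(kids2[[2]], u)
  # never exceeds the largest parental weight
  set.seed(4)
  for (rep in 1:50) {
    p1 <- random_weights(); p2 <- random_weights()
    kids3 <- domination_crossover(p1, p2)
    expect_lte(max(unlist(kids3)), max(c(p1, p2)) + 1e-12)
  }
})

test_that("mutation redraws and renormalises onto the simplex", {
  set.seed(9)
  g <- mutate_weights(c(0.2, 0.3, 0.5), "gentle")
  expect_equal(sum(g), 1)
  s <- mutate_weights(c(0.2, 0.3, 0.5), "super")
  expect_equal(sum(s), 1)
  set.seed(11); a <- mutate_weights(c(1, 0, 0), "gentle")
  set.seed(11); b <- mutate_weights(c(1, 0, 0), "gentle")
  expect_identical(a, b)   # seeded rng, reproducible
})

test_that("all operators map the simplex to itself", {
  set.seed(13)
  for (rep in 1:500) {
    p1 <- random_weights(); p2 <- random_weights()
    outs <- c(naive_crossover(p1, p2), domination_crossover(p1, p2),
              list(mutate_weights(p1, "gentle"),
                   mutate_weights(p2, "super")))
    for (w in outs) {
      expect_equal(sum(w), 1, tolerance = 1e-12)
      expect_true(all(w >= 0 & w <= 1))
    }
  }
})

test_that("a generation keeps the population size and the simplex", {
  ctx <- perfect_context()
  cfg <- ga_config(population_size = 20, generations = 10, runs = 1,
                   rng_seed = 5)
  set.seed(5)
  pop <- t(vapply(1:20, function(i) random_weights(3), numeric(3)))
  fit <- vapply(seq_len(nrow(pop)), function(i)
    ga_fitness(pop[i, ], ctx), numeric(1))
  nxt <- evolve_generation(pop, fit, cfg, generation = 1)
  expect_equal(dim(nxt), dim(pop))
  expect_equal(rowSums(nxt), rep(1, 20), tolerance = 1e-12)
  # too-small elite is a configuration error
  expect_error(evolve_generation(pop[1:4, ], fit[1:4], cfg),
               "at least 4")
})

test_that("seeded evolution is fully reproducible", {
  ctx <- perfect_context()
  cfg <- ga_config(population_size = 16, generations = 8, runs = 2,
                   rng_seed = 21)
  r1 <- run_ga(ctx, cfg)
  r2 <- run_ga(ctx, cfg)
  expect_identical(r1$best_weights, r2$best_weights)
  expect_identical(r1$history, r2$history)
  expect_equal(nrow(r1$history), 8)
})

test_that("best fitness is monotone non-decreasing under pure elitism", {
  ctx <- perfect_context()
  cfg <- ga_config(population_size = 20, generations = 30, runs = 1,
                   elite_mutation_prob = 0, rng_seed = 17)
  res <- run_ga(ctx, cfg)
  expect_true(all(diff(res$history$best) >= -1e-12))
})

test_that("zero generations fall back to the best random organism", {
  ctx <- perfect_context()
  cfg <- ga_config(population_size = 10, generations = 0, runs = 1,
                   rng_seed = 2)
  res <- run_ga(ctx, cfg)
  expect_equal(nrow(res$history), 0)
  expect_true(res$best_fitness >= 0 && res$best_fitness <= 1)
})

test_that("the GA recovers a perfectly separating extractor", {
  ctx <- perfect_context()
  cfg <- ga_config(population_size = 40, generations = 40, runs = 3,
                   rng_seed = 31)
  res <- run_ga(ctx, cfg)
  expect_gte(res$avg_fitness[["best"]], 0.99)
  # the separating extractor carries most of the learnt weight
  expect_gt(res$best_weights[1], 1 / 3)
})
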
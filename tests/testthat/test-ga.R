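test_that("mse_fitness is the mean squared voltage difference", {
  mk <- function(v) izhifit:::new_membrane_trace(seq_along(v) - 1, v,
                                                 rep(0, length(v)),
                                                 rep(0, length(v)))
  a <- mk(c(0, 1, 2))
  expect_identical(mse_fitness(a, a), 0)
  expect_identical(mse_fitness(mk(rep(2, 5)), mk(rep(0, 5))), 4)
  expect_equal(mse_fitness(mk(c(0, 1, 2)), mk(c(1, 1, 1))), 2 / 3)

  short <- mk(c(0, 1))
  expect_error(mse_fitness(a, short), "different time grids")
})

test_that("initial populations are uniform within bounds and reproducible", {
  cfg <- ga_config(population_size = 200, seed = 31)
  pop <- initialize_population(cfg)
  expect_identical(dim(pop), c(200L, 4L))
  for (j in 1:4) {
    expect_true(all(pop[, j] >= cfg$bounds[j, 1] &
                      pop[, j] <= cfg$bounds[j, 2]))
  }
  expect_identical(pop, initialize_population(cfg))

  # mean of 10,000 draws of 'a' under bounds [0.001, 0.2] within 3 SE of the
  # interval midpoint
  b <- default_bounds()
  b["a", ] <- c(0.001, 0.2)
  big <- initialize_population(ga_config(population_size = 10000, bounds = b,
                                         seed = 5))
  se <- (0.2 - 0.001) / sqrt(12 * 10000)
  expect_lt(abs(mean(big[, "a"]) - (0.001 + 0.2) / 2), 3 * se)
})

test_that("evolution preserves size and bounds and copies elites", {
  cfg <- ga_config(population_size = 40, seed = 2, mutation_rate = 1,
                   mutation_sd_frac = 0.5)
  set.seed(2)
  pop <- izhifit:::sample_population(cfg)
  fit <- runif(40)
  nxt <- evolve_generation(pop, fit, cfg)
  expect_identical(dim(nxt), dim(pop))
  for (j in 1:4) {
    expect_true(all(nxt[, j] >= cfg$bounds[j, 1] &
                      nxt[, j] <= cfg$bounds[j, 2]))
  }
  # elite individual survives unchanged
  expect_identical(nxt[1, ], pop[which.min(fit), ])

  # with no crossover and no mutation every offspring is a copied parent
  cfg0 <- ga_config(population_size = 40, seed = 2, crossover_fraction = 0,
                    mutation_rate = 0)
  nxt0 <- evolve_generation(pop, fit, cfg0)
  in_parents <- apply(nxt0, 1, function(r) {
    any(apply(pop, 1, function(p) all(p == r)))
  })
  expect_true(all(in_parents))
})

test_that("ga_config rejects out-of-range settings", {
  expect_error(ga_config(crossover_fraction = 1.7), "crossover_fraction")
  expect_error(ga_config(mutation_rate = -0.1), "mutation_rate")
  expect_error(ga_config(population_size = 1), "population_size")
  bad <- default_bounds(); bad[1, ] <- c(2, -1)
  expect_error(ga_config(bounds = bad), "low < high")
})

test_that("fitting is deterministic and monotone given a seed", {
  e <- tonic_entry()
  cfg_short <- sim_config(150)
  target <- make_target_trace(e$params, e$stimulus, cfg_short)$trace
  ga <- ga_config(population_size = 16, max_generations = 8, seed = 77,
                  bounds = bounds_around(e$params))
  f1 <- fit_izhikevich(target, e$stimulus, cfg_short, ga)
  f2 <- fit_izhikevich(target, e$stimulus, cfg_short, ga)
  expect_identical(f1$best_fitness, f2$best_fitness)
  expect_identical(as.numeric(f1$best_params), as.numeric(f2$best_params))
  expect_identical(f1$fitness_history, f2$fitness_history)
  expect_true(all(diff(f1$fitness_history) <= 0))
  expect_lte(f1$generations_run, 8)
  expect_length(f1$fitness_history, f1$generations_run)
})

test_that("a search box inside the truth's neighborhood reaches a low MSE", {
  e <- tonic_entry()
  cfg_short <- sim_config(150)
  target <- make_target_trace(e$params, e$stimulus, cfg_short)$trace
  ga <- ga_config(population_size = 20, max_generations = 12, seed = 4,
                  bounds = bounds_around(e$params, frac = 0.001,
                                         c_margin = 0.02))
  fr <- fit_izhikevich(target, e$stimulus, cfg_short, ga)
  expect_lt(fr$best_fitness, 20)
  rel <- abs(as.numeric(fr$best_params) - as.numeric(e$params)) /
    abs(as.numeric(e$params))
  expect_true(all(rel < 0.01))
})

test_that("divergent candidate regions are penalized, never fatal", {
  e <- tonic_entry()
  cfg_short <- sim_config(100)
  target <- make_target_trace(e$params, e$stimulus, cfg_short)$trace
  # a in [30, 60] destabilizes the recovery update at dt = 0.1
  bounds <- rbind(a = c(30, 60), b = c(-1.5, 0.4), c = c(-80, -40),
                  d = c(-25, 25))
  ga <- ga_config(population_size = 12, max_generations = 5, seed = 9,
                  bounds = bounds)
  fr <- fit_izhikevich(target, e$stimulus, cfg_short, ga)
  expect_identical(fr$generations_run, 5L)
  expect_true(is.finite(fr$best_fitness))
})

test_that("optional plateau stopping ends the run before the cap", {
  e <- tonic_entry()
  cfg_short <- sim_config(100)
  target <- make_target_trace(e$params, e$stimulus, cfg_short)$trace
  ga <- ga_config(population_size = 12, max_generations = 100, seed = 5,
                  bounds = bounds_around(e$params),
                  early_stop_tol = 1e-3, early_stop_patience = 5)
  fr <- fit_izhikevich(target, e$stimulus, cfg_short, ga)
  expect_lt(fr$generations_run, 100)
})

test_that("target grids that mismatch the simulation grid are rejected", {
  e <- tonic_entry()
  target <- make_target_trace(e$params, e$stimulus, sim_config(100))$trace
  expect_error(fit_izhikevich(target, e$stimulus, sim_config(200),
                              ga_config(population_size = 4,
                                        max_generations = 1)),
               "grid")
})
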
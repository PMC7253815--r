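#' Default genetic-algorithm search bounds
#'
#' Per-parameter intervals for (a, b, c, d) covering every published
#' canonical quadruple and the corresponding optimized quadruples with
#' margin.
#'
#' @return 4 x 2 matrix with rownames a, b, c, d and columns low, high
#' @export
default_bounds <- function() {
  m <- rbind(a = c(-0.1, 2), b = c(-1.5, 0.4), c = c(-80, -40),
             d = c(-25, 25))
  colnames(m) <- c("low", "high")
  m
}

#' Genetic-algorithm configuration
#'
#' Real-coded GA: tournament selection, arithmetic (blend) crossover
#' applied to a `crossover_fraction` share of offspring, per-gene Gaussian
#' mutation with probability `mutation_rate` and standard deviation
#' `mutation_sd_frac` of the bound width, clamping to bounds, and elitism.
#' The reference settings are crossover fraction 0.7, mutation rate 0.8 and
#' a 150-generation cap.
#'
#' @param population_size individuals per generation (>= 2)
#' @param crossover_fraction share of offspring produced by crossover, in
#'   \[0, 1\]
#' @param mutation_rate per-gene mutation probability, in \[0, 1\]
#' @param max_generations generation cap
#' @param bounds 4 x 2 matrix of per-parameter (low, high); see
#'   [default_bounds()]
#' @param elitism_count best individuals copied unchanged (>= 1 for a
#'   monotone best-fitness history)
#' @param tournament_size selection tournament size
#' @param seed RNG seed for the whole fit
#' @param mutation_sd_frac mutation sd as a fraction of bound width
#' @param early_stop_tol plateau tolerance; `NULL` (default) disables early
#'   stopping and the GA runs to `max_generations`
#' @param early_stop_patience unimproved generations before a plateau stop
#' @return a `ga_config`
#' @export
ga_config <- function(population_size = 60, crossover_fraction = 0.7,
                      mutation_rate = 0.8, max_generations = 150,
                      bounds = default_bounds(), elitism_count = 1,
                      tournament_size = 3, seed = 1,
                      mutation_sd_frac = 0.1, early_stop_tol = NULL,
                      early_stop_patience = 30) {
  if (population_size < 2) stop("population_size must be >= 2", call. = FALSE)
  if (crossover_fraction < 0 || crossover_fraction > 1) {
    stop("crossover_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must lie in [0, 1]", call. = FALSE)
  }
  if (elitism_count < 0 || elitism_count >= population_size) {
    stop("elitism_count must lie in [0, population_size)", call. = FALSE)
  }
  bounds <- as.matrix(bounds)
  if (!all(dim(bounds) == c(4, 2)) || any(bounds[, 1] >= bounds[, 2])) {
    stop("bounds must be a 4 x 2 matrix with low < high per parameter",
         call. = FALSE)
  }
  rownames(bounds) <- c("a", "b", "c", "d")
  structure(list(population_size = population_size,
                 crossover_fraction = crossover_fraction,
                 mutation_rate = mutation_rate,
                 max_generations = max_generations, bounds = bounds,
                 elitism_count = elitism_count,
                 tournament_size = tournament_size, seed = seed,
                 mutation_sd_frac = mutation_sd_frac,
                 early_stop_tol = early_stop_tol,
                 early_stop_patience = early_stop_patience),
            class = "ga_config")
}

#' Mean-square voltage error between two traces
#'
#' The GA's fitness: the mean over grid points of the squared voltage
#' difference (mV^2).  Both traces must live on the identical time grid;
#' there is no silent resampling.
#'
#' @param candidate,target `membrane_trace` objects on the same grid
#' @return scalar MSE in mV^2
#' @export
mse_fitness <- function(candidate, target) {
  stopifnot(inherits(candidate, "membrane_trace"),
            inherits(target, "membrane_trace"))
  if (length(candidate$times) != length(target$times) ||
      any(abs(candidate$times - target$times) > 1e-9)) {
    stop("candidate and target traces are on different time grids",
         call. = FALSE)
  }
  mean((candidate$v - target$v)^2)
}

#' Sample an initial population uniformly within bounds
#'
#' @param config a [ga_config()]; uses its `bounds`, `population_size`, and
#'   `seed`
#' @return `population_size x 4` matrix with columns a, b, c, d
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "ga_config"))
  set.seed(config$seed)
  sample_population(config)
}

sample_population <- function(config) {
  b <- config$bounds
  pop <- vapply(1:4, function(j) {
    runif(config$population_size, b[j, 1], b[j, 2])
  }, numeric(config$population_size))
  colnames(pop) <- rownames(b)
  pop
}

tournament_pick <- function(fitnesses, size) {
  idx <- sample.int(length(fitnesses), size, replace = TRUE)
  idx[which.min(fitnesses[idx])]
}

#' Produce the next GA generation
#'
#' Tournament selection of parents, arithmetic blend crossover on a
#' `crossover_fraction` share of offspring, per-gene Gaussian mutation,
#' clamping to bounds, and copying of the `elitism_count` best individuals
#' unchanged.  Population size is preserved.  Uses the current RNG stream
#' (seed once at the start of a fit).
#'
#' @param population matrix of individuals (rows)
#' @param fitnesses vector aligned with `population` rows (lower = better)
#' @param config a [ga_config()]
#' @return matrix of the same shape as `population`
#' @export
evolve_generation <- function(population, fitnesses, config) {
  stopifnot(nrow(population) == length(fitnesses))
  n <- nrow(population)
  b <- config$bounds
  widths <- b[, 2] - b[, 1]
  elite_idx <- order(fitnesses)[seq_len(config$elitism_count)]
  n_off <- n - config$elitism_count

  offspring <- matrix(0, nrow = n_off, ncol = ncol(population))
  for (i in seq_len(n_off)) {
    p1 <- population[tournament_pick(fitnesses, config$tournament_size), ]
    if (runif(1) < config$crossover_fraction) {
      p2 <- population[tournament_pick(fitnesses, config$tournament_size), ]
      alpha <- runif(ncol(population))
      child <- alpha * p1 + (1 - alpha) * p2
    } else {
      child <- p1
    }
    mut <- runif(length(child)) < config$mutation_rate
    if (any(mut)) {
      child[mut] <- child[mut] +
        rnorm(sum(mut), 0, config$mutation_sd_frac * widths[mut])
    }
    offspring[i, ] <- pmin(pmax(child, b[, 1]), b[, 2])
  }
  out <- rbind(population[elite_idx, , drop = FALSE], offspring)
  colnames(out) <- colnames(population)
  out
}

evaluate_population <- function(population, target, stimulus, sim_config) {
  penalty <- .Machine$double.xmax
  apply(population, 1, function(row) {
    p <- neuron_params(row[1], row[2], row[3], row[4])
    sim <- tryCatch(simulate_neuron(p, stimulus, sim_config),
                    error = function(e) NULL)
    if (is.null(sim)) return(penalty)
    mse_fitness(sim$trace, target)
  })
}

#' Fit neuron parameters to a target trace with the genetic algorithm
#'
#' Full GA loop: every candidate quadruple is simulated under the given
#' stimulus and config, scored by [mse_fitness()] against the target, and
#' the population evolved until the generation cap (or an optional fitness
#' plateau).  Candidates whose simulation diverges receive the largest
#' representable finite fitness and never abort the run.
#'
#' @param target a `membrane_trace` on the grid defined by `sim_config`
#' @param stimulus the `stimulus_protocol` the target was recorded under
#' @param sim_config the [sim_config()] used for candidate simulations
#' @param config a [ga_config()]
#' @return a `fit_result`: `best_params` ([neuron_params()]),
#'   `best_fitness` (mV^2), `fitness_history` (best-so-far per generation,
#'   non-increasing when elitism >= 1), `generations_run`, `config`
#' @export
fit_izhikevich <- function(target, stimulus, sim_config,
                           config = ga_config()) {
  stopifnot(inherits(target, "membrane_trace"),
            inherits(config, "ga_config"))
  n_target <- floor(sim_config$duration_ms / sim_config$dt_ms) + 1L
  if (length(target$times) != n_target) {
    stop("target grid does not match sim_config grid", call. = FALSE)
  }
  set.seed(config$seed)
  pop <- sample_population(config)
  fit <- evaluate_population(pop, target, stimulus, sim_config)
  best_i <- which.min(fit)
  best_row <- pop[best_i, ]
  best_fit <- fit[best_i]

  history <- numeric(0)
  gens <- 0L
  stall <- 0L
  for (g in seq_len(config$max_generations)) {
    pop <- evolve_generation(pop, fit, config)
    fit <- evaluate_population(pop, target, stimulus, sim_config)
    gens <- g
    gi <- which.min(fit)
    if (fit[gi] < best_fit) {
      improvement <- best_fit - fit[gi]
      best_fit <- fit[gi]
      best_row <- pop[gi, ]
      stall <- if (!is.null(config$early_stop_tol) &&
                   improvement < config$early_stop_tol) stall + 1L else 0L
    } else {
      stall <- stall + 1L
    }
    history <- c(history, best_fit)
    if (!is.null(config$early_stop_tol) &&
        stall >= config$early_stop_patience) break
  }
  structure(list(best_params = neuron_params(best_row[1], best_row[2],
                                             best_row[3], best_row[4]),
                 best_fitness = best_fit, fitness_history = history,
                 generations_run = gens, config = config),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  p <- x$best_params
  cat(sprintf(paste0("<fit_result> best MSE %.4g mV^2 after %d generations\n",
                     "  a=%.5g b=%.5g c=%.5g d=%.5g\n"),
              x$best_fitness, x$generations_run, p$a, p$b, p$c, p$d))
  invisible(x)
}

#' Bounds centered on a known quadruple
#'
#' Convenience for recovery experiments: a box spanning `±frac` relative on
#' (a, b, d) and `±c_margin` mV on c around a reference parameter set.
#'
#' @param params a [neuron_params()]
#' @param frac relative half-width on a, b, d
#' @param c_margin absolute half-width on c (mV)
#' @return 4 x 2 bounds matrix
#' @export
bounds_around <- function(params, frac = 0.5, c_margin = 10) {
  v <- as.numeric(params)
  lohi <- function(x) sort(c(x * (1 - frac), x * (1 + frac)))
  m <- rbind(a = lohi(v[1]), b = lohi(v[2]),
             c = c(v[3] - c_margin, v[3] + c_margin), d = lohi(v[4]))
  colnames(m) <- c("low", "high")
  m
}
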
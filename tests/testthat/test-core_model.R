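test_that("step_update reproduces hand-evaluated Euler steps", {
  tonic <- neuron_params(0.02, 0.2, -65, 6)

  # (v, u) = (-70, -14) zeroes both derivatives: 0.04*4900 - 350 + 140 + 14 = 0
  res <- step_update(list(v = -70, u = -14), tonic, I = 0, dt = 1)
  expect_equal(res$state$v, -70)
  expect_equal(res$state$u, -14)
  expect_false(res$spiked)

  # from (0, 0) with I = 10: dv = (140 + 10) * 0.1 = 15, du = 0
  res <- step_update(list(v = 0, u = 0), tonic, I = 10, dt = 0.1)
  expect_equal(res$state$v, 15)
  expect_equal(res$state$u, 0)
  expect_false(res$spiked)
})

test_that("step_update applies the after-spike reset exactly", {
  tonic <- neuron_params(0.02, 0.2, -65, 6)
  # a state whose update exceeds the +30 mV apex
  state <- list(v = 29, u = -20)
  res <- step_update(state, tonic, I = 10, dt = 0.5)
  expect_true(res$spiked)
  expect_identical(res$state$v, tonic$c)
  u_updated <- state$u + 0.5 * tonic$a * (tonic$b * state$v - state$u)
  expect_identical(res$state$u, u_updated + tonic$d)
  expect_identical(res$v_plot, 30)
})

test_that("reset semantics hold for randomized near-threshold states", {
  set.seed(42)
  for (i in 1:50) {
    p <- neuron_params(runif(1, 0.01, 1), runif(1, -1, 0.3),
                       runif(1, -70, -50), runif(1, -20, 20))
    state <- list(v = runif(1, 25, 29.9), u = runif(1, -30, 10))
    res <- step_update(state, p, I = runif(1, 0, 20), dt = 0.5)
    if (res$spiked) {
      expect_identical(res$state$v, p$c)
      u_upd <- state$u + 0.5 * p$a * (p$b * state$v - state$u)
      expect_identical(res$state$u, u_upd + p$d)
    }
  }
})

test_that("simulate_neuron matches the pure-R step_update reference", {
  # compiled and interpreted arithmetic may differ by fused-multiply-add
  # rounding, so agreement is to near machine precision, not bit level
  e <- tonic_entry()
  cfg <- sim_config(100)
  sim <- simulate_neuron(e$params, e$stimulus, cfg)
  ref <- r_reference_simulate(e$params, e$stimulus, cfg)
  expect_equal(sim$trace$v, ref$v, tolerance = 1e-9)
  expect_equal(sim$trace$u, ref$u, tolerance = 1e-9)
  expect_identical(sim$spikes$times_ms, ref$spikes)
})

test_that("canonical tonic simulation fires regularly under a current step", {
  e <- tonic_entry()
  sim <- simulate_neuron(e$params, e$stimulus, e$config)
  expect_gte(length(sim$spikes$times_ms), 5)
  isi <- diff(sim$spikes$times_ms)
  late <- tail(isi, 5)
  expect_lt(sd(late) / mean(late), 0.05)
})

test_that("zero input from the resting state produces no drift and no spikes", {
  p <- neuron_params(0.02, 0.2, -65, 6)
  cfg <- sim_config(500, v0 = -70, u0 = -14)
  sim <- simulate_neuron(p, baseline_stimulus(0), cfg)
  expect_length(sim$spikes$times_ms, 0)
  expect_lt(max(abs(sim$trace$v + 70)), 1e-6)
})

test_that("inhibition-induced parameters fire during a negative step", {
  e <- canonical_registry()[["inhibition-induced spiking"]]
  sim <- simulate_neuron(e$params, e$stimulus, e$config)
  seg <- e$stimulus$segments
  inside <- sim$spikes$times_ms >= seg$onset_ms & sim$spikes$times_ms < seg$offset_ms
  expect_gt(sum(inside), 3)
})

test_that("equilibria solves the fixed-point quadratic and classifies stability", {
  p <- neuron_params(0.02, 0.2, -65, 6)
  eq <- equilibria(p, I = 0)
  expect_equal(sort(eq$v), c(-70, -50))
  expect_true(eq$stable[which.min(eq$v)])   # -70 is the stable node
  expect_false(eq$stable[which.max(eq$v)])  # -50 is the saddle
  expect_equal(eq$u, p$b * eq$v)

  # b = 0.25: discriminant (4.75)^2 - 22.4 = 0.1625
  eq25 <- equilibria(neuron_params(0.02, 0.25, -65, 6), I = 0)
  stable_v <- (-(5 - 0.25) - sqrt(0.1625)) / 0.08
  expect_equal(eq25$v[eq25$stable], stable_v)
  expect_equal(eq25$v[eq25$stable], -64.41, tolerance = 1e-4)

  # I = 20: no fixed point, repetitive-firing regime
  expect_identical(nrow(equilibria(p, I = 20)), 0L)
})

test_that("simulating from a stable equilibrium stays there for a second", {
  for (e in canonical_registry()) {
    eq <- equilibria(e$params, I = e$stimulus$baseline)
    stable <- eq[eq$stable, , drop = FALSE]
    if (nrow(stable) == 0) next
    cfg <- sim_config(1000, v0 = stable$v[1], u0 = stable$u[1])
    sim <- simulate_neuron(e$params, baseline_stimulus(e$stimulus$baseline),
                           cfg)
    expect_length(sim$spikes$times_ms, 0)
    expect_lt(max(abs(sim$trace$v - stable$v[1])), 1e-6)
  }
})

test_that("registry holds the eight canonical patterns with printed values", {
  reg <- canonical_registry()
  expect_length(reg, 8)
  expect_setequal(names(reg),
                  c("tonic spiking", "mixed spiking", "integrator",
                    "depolarizing", "phasic spiking", "rebound spiking",
                    "threshold variability", "inhibition-induced spiking"))
  expect_equal(as.numeric(reg[["tonic spiking"]]$params),
               c(0.02, 0.2, -65, 6))
  expect_equal(as.numeric(reg[["depolarizing"]]$params),
               c(1, 0.2, -60, -21))
  for (e in reg) {
    expect_s3_class(e$stimulus, "stimulus_protocol")
    expect_s3_class(e$config, "sim_config")
  }
})

test_that("halving dt changes the tonic spike count by at most one", {
  e <- tonic_entry()
  n1 <- length(simulate_neuron(e$params, e$stimulus,
                               sim_config(500, dt_ms = 0.1))$spikes$times_ms)
  n2 <- length(simulate_neuron(e$params, e$stimulus,
                               sim_config(500, dt_ms = 0.05))$spikes$times_ms)
  expect_lte(abs(n1 - n2), 1)
})

test_that("identical inputs give bit-identical traces", {
  e <- tonic_entry()
  s1 <- simulate_neuron(e$params, e$stimulus, e$config)
  s2 <- simulate_neuron(e$params, e$stimulus, e$config)
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$spikes, s2$spikes)
})

test_that("numerical blow-up raises a divergence error naming the step", {
  # a = 40 makes the recovery update unstable at dt = 0.1 (growth factor -3)
  p <- neuron_params(40, 0.2, -65, 6)
  cfg <- sim_config(1000, v0 = -60)
  expect_error(simulate_neuron(p, stim_step(10, 0, 1000), cfg),
               "divergence at step")
})

test_that("trace grids have floor(duration/dt) + 1 samples and clip at peak", {
  e <- tonic_entry()
  sim <- simulate_neuron(e$params, e$stimulus, e$config)
  expect_length(sim$trace$times, floor(500 / 0.1) + 1)
  expect_lte(max(sim$trace$v), 30)
})
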
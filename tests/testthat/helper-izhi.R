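# shared fixtures and independent oracles

tonic_entry <- function() canonical_registry()[["tonic spiking"]]

# baseline-only protocol (no active segments) at a given holding current
baseline_stimulus <- function(baseline = 0) {
  stim_custom(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                         amplitude = numeric(0)),
              baseline = baseline)
}

# independent O(n^2) correlogram oracle: enumerate every pair
brute_correlogram <- function(ref, tgt, bin_ms, window_ms,
                              auto = identical(ref, tgt)) {
  edges <- seq(-window_ms, window_ms, by = bin_ms)
  counts <- integer(length(edges) - 1L)
  for (i in seq_along(ref)) {
    for (j in seq_along(tgt)) {
      if (auto && i == j) next
      d <- tgt[j] - ref[i]
      if (d < -window_ms || d > window_ms) next
      bin <- findInterval(d, edges, rightmost.closed = TRUE)
      counts[bin] <- counts[bin] + 1L
    }
  }
  counts
}

# pure-R forward-Euler reference built on step_update(), independent of the
# compiled simulation path
r_reference_simulate <- function(params, stimulus, config) {
  n <- floor(config$duration_ms / config$dt_ms) + 1L
  times <- (seq_len(n) - 1L) * config$dt_ms
  current <- stimulus_current(stimulus, times)
  init <- izhifit:::resolve_initial_state(params, stimulus, config)
  state <- list(v = init[["v0"]], u = init[["u0"]])
  v <- numeric(n); u <- numeric(n); spikes <- numeric(0)
  v[1] <- state$v; u[1] <- state$u
  for (i in 2:n) {
    res <- step_update(state, params, current[i - 1L], config$dt_ms,
                       config$peak_cutoff)
    v[i] <- res$v_plot
    u[i] <- res$state$u
    if (res$spiked) spikes <- c(spikes, times[i])
    state <- res$state
  }
  list(times = times, v = v, u = u, spikes = spikes)
}
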
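#' Neuron parameter quadruple
#'
#' The four dimensionless parameters of the two-variable quadratic
#' spiking-neuron model: `a` sets the time scale of the recovery variable
#' (smaller = slower recovery), `b` the sensitivity of recovery to
#' subthreshold voltage fluctuations, `c` the after-spike reset voltage
#' (mV), and `d` the after-spike increment of the recovery variable.
#'
#' @param a recovery time-scale
#' @param b recovery sensitivity to voltage
#' @param c after-spike reset voltage (mV)
#' @param d after-spike recovery increment
#' @return an object of class `neuron_params`
#' @export
#' @examples
#' neuron_params(0.02, 0.2, -65, 6)  # tonic spiking
neuron_params <- function(a, b, c, d) {
  vals <- c(a = a, b = b, c = c, d = d)
  if (!all(is.finite(vals))) {
    stop("all four parameters must be finite", call. = FALSE)
  }
  structure(as.list(vals), class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<neuron_params> a=%g b=%g c=%g d=%g\n", x$a, x$b, x$c, x$d))
  invisible(x)
}

#' @export
as.numeric.neuron_params <- function(x, ...) {
  c(x$a, x$b, x$c, x$d)
}

## ---------------------------------------------------------------------------
## Stimulus protocols
##
## A protocol is a baseline current plus additive rectangular (or ramp)
## segments.  `probe`/`probe_window_ms`/`control_window_ms` tag protocols
## designed to test integration or threshold variability: a label that needs
## a specific probe is only reachable when the protocol declares it.

stim_kinds <- c("step", "pulse", "paired_pulse", "ramp",
                "negative_step", "custom_series")

new_stimulus <- function(kind, segments, baseline = 0, probe = "none",
                         probe_window_ms = NULL, control_window_ms = NULL) {
  stopifnot(kind %in% stim_kinds)
  segments <- as.data.frame(segments)
  if (nrow(segments) > 0) {
    stopifnot(all(c("onset_ms", "offset_ms", "amplitude") %in% names(segments)))
    if (any(!is.finite(as.matrix(segments)))) {
      stop("stimulus segments must be finite", call. = FALSE)
    }
    if (any(segments$onset_ms >= segments$offset_ms)) {
      stop("each segment needs onset_ms < offset_ms", call. = FALSE)
    }
  }
  structure(list(kind = kind, segments = segments, baseline = baseline,
                 probe = probe, probe_window_ms = probe_window_ms,
                 control_window_ms = control_window_ms),
            class = "stimulus_protocol")
}

#' Stimulus protocol constructors
#'
#' Build the injected-current protocols used to elicit the canonical firing
#' patterns: sustained steps, brief pulses, paired-pulse integration probes,
#' ramps, negative (hyperpolarizing) steps, and free-form segment series.
#' Currents are in the dimensionless input units of the model's voltage
#' equation; times in ms.  Segment amplitudes add to `baseline`.
#'
#' @param amplitude segment current amplitude (added to baseline)
#' @param onset_ms,offset_ms segment window
#' @param baseline holding current outside all segments
#' @param width_ms pulse width
#' @param gap_ms gap between the two pulses of the close (probe) pair
#' @param control_onset_ms,control_gap_ms placement of the widely spaced
#'   control pair that should fail to summate
#' @param step_amplitude current during a negative step (absolute value,
#'   typically below `baseline`)
#' @param segments data.frame with columns onset_ms, offset_ms, amplitude
#' @param probe probe tag, one of "none", "integrator", "threshold"
#' @param probe_window_ms,control_window_ms length-2 windows in which the
#'   designed probe should / should not elicit spikes
#' @return a `stimulus_protocol`
#' @name stimulus
NULL

#' @rdname stimulus
#' @export
stim_step <- function(amplitude, onset_ms, offset_ms, baseline = 0) {
  new_stimulus("step",
               data.frame(onset_ms = onset_ms, offset_ms = offset_ms,
                          amplitude = amplitude),
               baseline = baseline)
}

#' @rdname stimulus
#' @export
stim_pulse <- function(amplitude, onset_ms, width_ms, baseline = 0) {
  new_stimulus("pulse",
               data.frame(onset_ms = onset_ms, offset_ms = onset_ms + width_ms,
                          amplitude = amplitude),
               baseline = baseline)
}

#' @rdname stimulus
#' @export
stim_paired_pulse <- function(amplitude, onset_ms, width_ms, gap_ms,
                              control_onset_ms = NULL,
                              control_gap_ms = NULL, baseline = 0) {
  on2 <- onset_ms + width_ms + gap_ms
  seg <- data.frame(onset_ms = c(onset_ms, on2),
                    offset_ms = c(onset_ms, on2) + width_ms,
                    amplitude = amplitude)
  probe_win <- c(onset_ms, on2 + width_ms + 25)
  ctrl_win <- NULL
  if (!is.null(control_onset_ms)) {
    if (is.null(control_gap_ms)) control_gap_ms <- 5 * gap_ms
    con2 <- control_onset_ms + width_ms + control_gap_ms
    seg <- rbind(seg, data.frame(onset_ms = c(control_onset_ms, con2),
                                 offset_ms = c(control_onset_ms, con2) + width_ms,
                                 amplitude = amplitude))
    ctrl_win <- c(control_onset_ms, con2 + width_ms + 25)
  }
  new_stimulus("paired_pulse", seg, baseline = baseline, probe = "integrator",
               probe_window_ms = probe_win, control_window_ms = ctrl_win)
}

#' @rdname stimulus
#' @export
stim_ramp <- function(amplitude, onset_ms, offset_ms, baseline = 0) {
  new_stimulus("ramp",
               data.frame(onset_ms = onset_ms, offset_ms = offset_ms,
                          amplitude = amplitude),
               baseline = baseline)
}

#' @rdname stimulus
#' @export
stim_negative_step <- function(step_amplitude, onset_ms, offset_ms, baseline) {
  new_stimulus("negative_step",
               data.frame(onset_ms = onset_ms, offset_ms = offset_ms,
                          amplitude = step_amplitude - baseline),
               baseline = baseline)
}

#' @rdname stimulus
#' @export
stim_custom <- function(segments, baseline = 0, probe = "none",
                        probe_window_ms = NULL, control_window_ms = NULL) {
  new_stimulus("custom_series", segments, baseline = baseline, probe = probe,
               probe_window_ms = probe_window_ms,
               control_window_ms = control_window_ms)
}

#' Evaluate a stimulus protocol on a time grid
#'
#' @param stimulus a `stimulus_protocol`
#' @param times_ms numeric vector of times (ms)
#' @return current at each time; segments are active on `[onset, offset)`
#' @export
stimulus_current <- function(stimulus, times_ms) {
  stopifnot(inherits(stimulus, "stimulus_protocol"))
  out <- rep(stimulus$baseline, length(times_ms))
  seg <- stimulus$segments
  if (nrow(seg) == 0) return(out)
  for (i in seq_len(nrow(seg))) {
    active <- times_ms >= seg$onset_ms[i] & times_ms < seg$offset_ms[i]
    if (stimulus$kind == "ramp") {
      frac <- (times_ms[active] - seg$onset_ms[i]) /
        (seg$offset_ms[i] - seg$onset_ms[i])
      out[active] <- out[active] + seg$amplitude[i] * frac
    } else {
      out[active] <- out[active] + seg$amplitude[i]
    }
  }
  if (any(!is.finite(out))) stop("stimulus evaluated to non-finite current")
  out
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> kind=%s baseline=%g segments=%d\n",
              x$kind, x$baseline, nrow(x$segments)))
  invisible(x)
}

## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' @param duration_ms total simulated time (ms)
#' @param dt_ms forward-Euler step (ms); default 0.1 trades speed for
#'   accuracy relative to the model's original 1 ms convention
#' @param v0,u0 initial state; `NULL` means "resolve at simulation time" to
#'   the stable equilibrium under the baseline current when one exists,
#'   otherwise `(c, b*c)`
#' @param peak_cutoff spike apex (mV) that triggers the after-spike reset;
#'   +30 by construction of the model, configurable only for sensitivity
#'   tests
#' @return a `sim_config`
#' @export
sim_config <- function(duration_ms, dt_ms = 0.1, v0 = NULL, u0 = NULL,
                       peak_cutoff = 30) {
  if (!is.finite(dt_ms) || dt_ms <= 0) stop("dt_ms must be > 0", call. = FALSE)
  if (!is.finite(duration_ms) || duration_ms < dt_ms) {
    stop("duration_ms must be >= dt_ms", call. = FALSE)
  }
  structure(list(duration_ms = duration_ms, dt_ms = dt_ms, v0 = v0, u0 = u0,
                 peak_cutoff = peak_cutoff), class = "sim_config")
}

resolve_initial_state <- function(params, stimulus, config) {
  v0 <- config$v0
  u0 <- config$u0
  if (is.null(v0)) {
    eq <- equilibria(params, I = stimulus$baseline)
    stable <- eq[eq$stable, , drop = FALSE]
    if (nrow(stable) > 0) {
      v0 <- stable$v[1]
      if (is.null(u0)) u0 <- stable$u[1]
    } else {
      v0 <- params$c
    }
  }
  if (is.null(u0)) u0 <- params$b * v0
  c(v0 = v0, u0 = u0)
}

#' Single forward-Euler update with after-spike reset
#'
#' Advances the state (v, u) by one step of the quadratic voltage equation
#' `dv/dt = 0.04 v^2 + 5 v + 140 - u + I` and the linear recovery equation
#' `du/dt = a (b v - u)`.  If the updated voltage reaches `peak_cutoff`, the
#' spike reset is applied: v <- c, u <- u + d.
#'
#' @param state list or named vector with elements `v` and `u`
#' @param params a [neuron_params()]
#' @param I injected current over the step
#' @param dt step size (ms), > 0
#' @param peak_cutoff spike apex (mV), default +30
#' @return list with `state` (the post-step, post-reset state), `spiked`
#'   (logical), and `v_plot` (the value to store at this sample: the clipped
#'   apex on a spike sample, otherwise the updated voltage)
#' @export
step_update <- function(state, params, I, dt, peak_cutoff = 30) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  v <- state$v
  u <- state$u
  if (!all(is.finite(c(v, u, I)))) stop("state and current must be finite",
                                        call. = FALSE)
  nv <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
  nu <- u + dt * params$a * (params$b * v - u)
  if (!is.finite(nv) || !is.finite(nu)) {
    stop("divergence in step_update: non-finite state after update",
         call. = FALSE)
  }
  if (nv >= peak_cutoff) {
    list(state = list(v = params$c, u = nu + params$d), spiked = TRUE,
         v_plot = peak_cutoff)
  } else {
    list(state = list(v = nv, u = nu), spiked = FALSE, v_plot = nv)
  }
}

#' Simulate the neuron over a stimulus protocol
#'
#' Integrates the model with forward Euler on a uniform grid of
#' `floor(duration/dt) + 1` points.  Spike samples are stored clipped at
#' `peak_cutoff`; the carried state is reset to `(c, u + d)`.  Deterministic:
#' identical inputs give bit-identical traces.
#'
#' @param params a [neuron_params()]
#' @param stimulus a `stimulus_protocol`
#' @param config a [sim_config()]
#' @return list with `trace` (a `membrane_trace`: times, v, u, I) and
#'   `spikes` (a [spike_train()] of the spike-sample times)
#' @export
simulate_neuron <- function(params, stimulus, config) {
  stopifnot(inherits(params, "neuron_params"),
            inherits(stimulus, "stimulus_protocol"),
            inherits(config, "sim_config"))
  n <- floor(config$duration_ms / config$dt_ms) + 1L
  times <- (seq_len(n) - 1L) * config$dt_ms
  current <- stimulus_current(stimulus, times)
  init <- resolve_initial_state(params, stimulus, config)
  res <- izhi_simulate_cpp(params$a, params$b, params$c, params$d,
                           current, config$dt_ms, init[["v0"]], init[["u0"]],
                           config$peak_cutoff)
  if (isTRUE(res$diverged)) {
    stop(sprintf("divergence at step %d (t = %.3f ms): non-finite state",
                 res$step, times[res$step + 1L]), call. = FALSE)
  }
  trace <- new_membrane_trace(times, res$v, res$u, current,
                              peak_cutoff = config$peak_cutoff)
  spikes <- spike_train(times[res$spike_idx + 1L],
                        duration_ms = config$duration_ms)
  list(trace = trace, spikes = spikes)
}

new_membrane_trace <- function(times, v, u, I, peak_cutoff = 30) {
  stopifnot(length(times) == length(v), length(v) == length(u),
            length(u) == length(I))
  structure(list(times = times, v = v, u = u, I = I),
            class = "membrane_trace", peak_cutoff = peak_cutoff)
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf("<membrane_trace> %d samples over %.1f ms (dt=%.3g), v in [%.1f, %.1f]\n",
              length(x$times), max(x$times), x$times[2] - x$times[1],
              min(x$v), max(x$v)))
  invisible(x)
}

#' Sorted spike-timestamp container
#'
#' @param times_ms strictly increasing timestamps (ms)
#' @param duration_ms recording span (ms); every timestamp must lie in
#'   `[0, duration_ms]`
#' @return a `spike_train`
#' @export
spike_train <- function(times_ms, duration_ms) {
  times_ms <- as.numeric(times_ms)
  if (length(times_ms) > 1 && any(diff(times_ms) <= 0)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  if (length(times_ms) > 0 &&
      (min(times_ms) < 0 || max(times_ms) > duration_ms)) {
    stop("spike times must lie within [0, duration_ms]", call. = FALSE)
  }
  structure(list(times_ms = times_ms, duration_ms = duration_ms),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.1f ms (%.2f Hz)\n",
              length(x$times_ms), x$duration_ms,
              1000 * length(x$times_ms) / x$duration_ms))
  invisible(x)
}

#' Fixed points of the subthreshold system
#'
#' Solves `0.04 v^2 + (5 - b) v + (140 + I) = 0` for the equilibria of the
#' continuous (no-reset) dynamics, with `u* = b v*`, and classifies the
#' stability of each from the eigenvalues of the Jacobian.  An empty result
#' (negative discriminant) means the model fires repetitively at that
#' current.
#'
#' @param params a [neuron_params()] (only `a` and `b` enter)
#' @param I injected current
#' @return data.frame with columns `v`, `u`, `stable` (0 rows when no real
#'   fixed point exists)
#' @export
#' @examples
#' equilibria(neuron_params(0.02, 0.2, -65, 6), I = 0)  # -70 stable, -50 saddle
equilibria <- function(params, I = 0) {
  b <- params$b
  a <- params$a
  disc <- (5 - b)^2 - 4 * 0.04 * (140 + I)
  if (disc < 0) {
    return(data.frame(v = numeric(0), u = numeric(0), stable = logical(0)))
  }
  v_roots <- (-(5 - b) + c(-1, 1) * sqrt(disc)) / (2 * 0.04)
  stable <- vapply(v_roots, function(v) {
    J <- matrix(c(0.08 * v + 5, -1, a * b, -a), 2, 2, byrow = TRUE)
    all(Re(eigen(J, only.values = TRUE)$values) < 0)
  }, logical(1))
  data.frame(v = v_roots, u = b * v_roots, stable = stable)
}

## ---------------------------------------------------------------------------

#' Registry of canonical firing-pattern configurations
#'
#' The eight named patterns with their published parameter quadruples, each
#' paired with a stimulus protocol that elicits the pattern and a simulation
#' config.  Protocols follow the conventional published pattern gallery:
#' sustained step for tonic/phasic/mixed firing, paired pulses for the
#' integrator, a priming-inhibition probe for threshold variability, a brief
#' hyperpolarizing pulse for rebound, a sustained negative step for
#' inhibition-induced firing, and a brief suprathreshold pulse for the
#' depolarizing after-potential (DAP).
#'
#' Each entry has `name` (registry key), `label` (the classifier-vocabulary
#' name the pattern maps to), `params`, `stimulus`, `config`.
#'
#' @return named list of 8 entries
#' @export
#' @examples
#' reg <- canonical_registry()
#' reg[["tonic spiking"]]$params
canonical_registry <- function() {
  entry <- function(name, label, params, stimulus, config) {
    list(name = name, label = label, params = params, stimulus = stimulus,
         config = config)
  }
  reg <- list(
    entry("tonic spiking", "tonic spiking",
          neuron_params(0.02, 0.2, -65, 6),
          stim_step(10, onset_ms = 20, offset_ms = 500),
          sim_config(500)),
    entry("mixed spiking", "mixed mode",
          neuron_params(0.02, 0.2, -55, 4),
          stim_step(10, onset_ms = 20, offset_ms = 500),
          sim_config(500)),
    entry("integrator", "integrator",
          neuron_params(0.02, -0.1, -55, 6),
          stim_paired_pulse(40, onset_ms = 10, width_ms = 2, gap_ms = 2,
                            control_onset_ms = 60, control_gap_ms = 10),
          # published gallery operating point; the subthreshold equilibrium
          # for b = -0.1 sits near -87.5 mV, far below where the pattern runs
          sim_config(120, v0 = -60)),
    entry("depolarizing", "DAP",
          neuron_params(1, 0.2, -60, -21),
          stim_pulse(12, onset_ms = 9, width_ms = 2),
          sim_config(80)),
    entry("phasic spiking", "phasic spiking",
          neuron_params(0.02, 0.25, -65, 6),
          stim_step(0.5, onset_ms = 20, offset_ms = 300),
          sim_config(300)),
    entry("rebound spiking", "rebound spike",
          neuron_params(0.03, 0.25, -60, 4),
          stim_pulse(-15, onset_ms = 20, width_ms = 5),
          sim_config(200)),
    entry("threshold variability", "threshold variability",
          neuron_params(0.03, 0.25, -60, 4),
          stim_custom(data.frame(onset_ms = c(10, 70, 80),
                                 offset_ms = c(15, 75, 85),
                                 amplitude = c(1, -6, 1)),
                      probe = "threshold",
                      probe_window_ms = c(80, 110),
                      control_window_ms = c(10, 40)),
          sim_config(150)),
    entry("inhibition-induced spiking", "inhibition-induced spiking",
          neuron_params(-0.02, -1, -60, 8),
          stim_negative_step(75, onset_ms = 50, offset_ms = 300, baseline = 80),
          sim_config(350))
  )
  names(reg) <- vapply(reg, `[[`, character(1), "name")
  reg
}

#' Reference optimized parameter quadruples
#'
#' Optimized (a, b, c, d) values reported for rat basolateral-amygdala and
#' hippocampus single-unit activity, one per canonical pattern, obtained by
#' genetic-algorithm refinement of the canonical quadruples against recorded
#' membrane traces.  Useful as realistic "after optimization" inputs for
#' stability and simulation checks; the recordings behind them are not
#' redistributable, so these values are inputs here, not reproduced outputs.
#'
#' @return named list of [neuron_params()], keyed like
#'   [canonical_registry()]
#' @export
reference_optimized_params <- function() {
  list(
    "tonic spiking"              = neuron_params(0.01877, 0.26801, -66.3083, 12.46620),
    "mixed spiking"              = neuron_params(0.037413, 0.19586, -56.165, 10.82459),
    "integrator"                 = neuron_params(0.1975, -0.1025, -59.874, 12.16331),
    "depolarizing"               = neuron_params(1.738625, 0.165259, -67.823, -4.4429),
    "phasic spiking"             = neuron_params(0.023135, 0.24904, -67.904, 19.35829),
    "rebound spiking"            = neuron_params(0.038877, 0.25154, -64.0123, 11.09948),
    "threshold variability"      = neuron_params(0.067733, 0.251266, -62.2565, 13.03464),
    "inhibition-induced spiking" = neuron_params(0.0090563, -1.14721, -62.0312, 16.2566)
  )
}
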
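#' Noisy target trace with known ground truth
#'
#' Simulates the model and adds i.i.d. Gaussian voltage noise, carrying the
#' generating quadruple alongside so parameter-recovery experiments can be
#' scored against truth.  Emulates a recorded membrane-potential comparison
#' curve.
#'
#' @param params the generating [neuron_params()]
#' @param stimulus a `stimulus_protocol`
#' @param sim_config a [sim_config()]
#' @param noise_sd_mv Gaussian noise sd (mV); 0 gives the clean simulation
#' @param seed RNG seed
#' @return list with `trace` (noisy `membrane_trace`), `clean` (noiseless),
#'   `spikes` (the clean [spike_train()]), `truth` (= `params`)
#' @export
make_target_trace <- function(params, stimulus, sim_config, noise_sd_mv = 0,
                              seed = 1) {
  stopifnot(noise_sd_mv >= 0)
  sim <- simulate_neuron(params, stimulus, sim_config)
  noisy <- sim$trace
  if (noise_sd_mv > 0) {
    set.seed(seed)
    noisy$v <- noisy$v + rnorm(length(noisy$v), 0, noise_sd_mv)
  }
  list(trace = noisy, clean = sim$trace, spikes = sim$spikes, truth = params)
}

#' Default biphasic spike template
#'
#' A 1.2 ms extracellular spike shape: sharp negative valley followed by a
#' shallower positive overshoot, normalized so the valley is -1.  Matches
#' the negative-threshold convention of [detect_spikes()].
#'
#' @param fs_hz sampling rate
#' @param width_ms template duration
#' @return numeric vector of length `round(width_ms * fs_hz / 1000)`
#' @export
biphasic_template <- function(fs_hz = 50000, width_ms = 1.2) {
  n <- round(width_ms * fs_hz / 1000)
  t <- seq(0, width_ms, length.out = n)
  w <- -exp(-((t - 0.30) / 0.10)^2) + 0.45 * exp(-((t - 0.62) / 0.18)^2)
  w / max(abs(w))
}

#' Specification of one synthetic unit
#'
#' @param drive either `list(kind = "poisson", rate_hz, refractory_ms)` or
#'   `list(kind = "izhikevich", params, stimulus, config)`
#' @param amplitude_uv peak absolute amplitude of the unit's waveform (uV)
#' @param template normalized waveform (max |.| = 1); default
#'   [biphasic_template()]
#' @param fs_hz sampling rate the template is built for
#' @return a `unit_spec`
#' @export
unit_spec <- function(drive, amplitude_uv, template = NULL, fs_hz = 50000) {
  if (is.null(template)) template <- biphasic_template(fs_hz)
  if (length(template) < 8) stop("template needs >= 8 samples", call. = FALSE)
  if (identical(drive$kind, "poisson") &&
      (is.null(drive$refractory_ms) || drive$refractory_ms < 1)) {
    stop("poisson drive needs refractory_ms >= 1", call. = FALSE)
  }
  structure(list(drive = drive, amplitude_uv = amplitude_uv,
                 template = template), class = "unit_spec")
}

#' Homogeneous Poisson spike train with a refractory period
#'
#' Draws a homogeneous Poisson process at `rate_hz` and thins it
#' sequentially: any spike closer than `refractory_ms` to the previously
#' accepted spike is removed.
#'
#' @param rate_hz expected rate before thinning (>= 0)
#' @param duration_s train length (s)
#' @param refractory_ms minimum ISI after thinning
#' @param seed RNG seed
#' @return a [spike_train()] (times in ms)
#' @export
make_poisson_train <- function(rate_hz, duration_s, refractory_ms = 1,
                               seed = 1) {
  stopifnot(rate_hz >= 0, duration_s > 0)
  dur_ms <- duration_s * 1000
  if (rate_hz == 0) return(spike_train(numeric(0), duration_ms = dur_ms))
  set.seed(seed)
  # oversample ISIs, then walk forward applying the refractory rule
  n_guess <- max(10, ceiling(rate_hz * duration_s * 1.5 +
                               5 * sqrt(rate_hz * duration_s)))
  times <- cumsum(rexp(n_guess, rate_hz)) * 1000
  while (length(times) > 0 && times[length(times)] < dur_ms) {
    extra <- cumsum(rexp(n_guess, rate_hz)) * 1000 + times[length(times)]
    times <- c(times, extra)
  }
  times <- times[times < dur_ms]
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory_ms) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  spike_train(times[keep], duration_ms = dur_ms)
}

draw_unit_times <- function(unit, duration_s, seed) {
  d <- unit$drive
  if (identical(d$kind, "poisson")) {
    make_poisson_train(d$rate_hz, duration_s, d$refractory_ms, seed)$times_ms
  } else if (identical(d$kind, "izhikevich")) {
    simulate_neuron(d$params, d$stimulus, d$config)$spikes$times_ms
  } else {
    stop("unknown drive kind: ", d$kind, call. = FALSE)
  }
}

#' Synthetic multi-unit extracellular recording
#'
#' For each unit, spike times are drawn from its drive and its scaled
#' template is added to the signal at those times (overlaps sum); white
#' Gaussian background noise is added on top.  The exact inserted times and
#' templates are stored as ground truth.
#'
#' @param units list of [unit_spec()]s
#' @param duration_s recording length (s)
#' @param fs_hz sampling rate; must exceed twice the 10 kHz spike band
#' @param noise_sd_uv background noise sd (uV)
#' @param seed RNG seed (per-unit draws and noise are derived from it)
#' @return an [extracellular_recording()] with `ground_truth`
#' @export
make_extracellular <- function(units, duration_s, fs_hz = 50000,
                               noise_sd_uv = 0, seed = 1) {
  stopifnot(fs_hz > 2 * 10000, duration_s > 0)
  n <- round(fs_hz * duration_s)
  signal <- numeric(n)
  gt <- list()
  for (ui in seq_along(units)) {
    unit <- units[[ui]]
    if (length(unit$template) >= n) {
      stop("unit template longer than the recording", call. = FALSE)
    }
    times_ms <- draw_unit_times(unit, duration_s, seed = seed + ui)
    tpl <- unit$template * unit$amplitude_uv
    # drop spikes whose template would run off the end
    max_start <- n - length(tpl) + 1L
    starts <- round(times_ms / 1000 * fs_hz) + 1L
    ok <- starts >= 1L & starts <= max_start
    times_ms <- times_ms[ok]
    for (s in starts[ok]) {
      idx <- s:(s + length(tpl) - 1L)
      signal[idx] <- signal[idx] + tpl
    }
    gt[[paste0("unit_", ui)]] <- list(times_ms = times_ms, template = tpl)
  }
  if (noise_sd_uv > 0) {
    set.seed(seed)
    signal <- signal + rnorm(n, 0, noise_sd_uv)
  }
  extracellular_recording(signal, fs_hz = fs_hz, ground_truth = gt)
}

#' The standard 3-unit synthetic recording
#'
#' The package's reference sorting fixture: 60 s at 50 kHz, three
#' Poisson-driven units at 2, 5, and 8 Hz with peak amplitudes 80, 100, and
#' 120 uV, 2 ms refractory periods, and 16 uV white background noise
#' (peak-amplitude SNR 5--7.5).  Mirrors a 3-cluster single-channel
#' recording at desk scale.
#'
#' @param seed RNG seed (default 1234)
#' @param duration_s recording length
#' @param noise_sd_uv background noise sd
#' @return an [extracellular_recording()] with ground truth
#' @export
standard_recording <- function(seed = 1234, duration_s = 60,
                               noise_sd_uv = 16) {
  fs <- 50000
  units <- list(
    unit_spec(list(kind = "poisson", rate_hz = 2, refractory_ms = 2),
              amplitude_uv = 80,
              template = biphasic_width_variant(fs, 0.8), fs_hz = fs),
    unit_spec(list(kind = "poisson", rate_hz = 5, refractory_ms = 2),
              amplitude_uv = 100,
              template = triphasic_template(fs), fs_hz = fs),
    unit_spec(list(kind = "poisson", rate_hz = 8, refractory_ms = 2),
              amplitude_uv = 120,
              template = biphasic_width_variant(fs, 1.35), fs_hz = fs)
  )
  make_extracellular(units, duration_s = duration_s, fs_hz = fs,
                     noise_sd_uv = noise_sd_uv, seed = seed)
}

# widen/narrow the default biphasic shape so units differ in waveform, not
# just amplitude
biphasic_width_variant <- function(fs_hz, stretch) {
  n <- round(1.2 * fs_hz / 1000)
  t <- seq(0, 1.2, length.out = n)
  w <- -exp(-((t - 0.30 * stretch) / (0.10 * stretch))^2) +
    0.45 * exp(-((t - 0.62 * stretch) / (0.18 * stretch))^2)
  w / max(abs(w))
}

# triphasic shape (positive prepotential, sharp valley, slow overshoot), a
# second standard extracellular waveform family
triphasic_template <- function(fs_hz, width_ms = 1.2) {
  n <- round(width_ms * fs_hz / 1000)
  t <- seq(0, width_ms, length.out = n)
  w <- 0.35 * exp(-((t - 0.14) / 0.07)^2) -
    exp(-((t - 0.38) / 0.09)^2) +
    0.30 * exp(-((t - 0.75) / 0.22)^2)
  w / max(abs(w))
}
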
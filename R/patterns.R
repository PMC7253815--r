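#' Firing-pattern vocabulary
#'
#' The closed set of 20 pattern names used for classification and reporting,
#' plus the two bookkeeping labels `quiescent` (no spikes) and
#' `unclassified` (no rule fired).
#'
#' @param extended include `quiescent` and `unclassified`
#' @return character vector
#' @export
pattern_vocabulary <- function(extended = FALSE) {
  voc <- c("tonic spiking", "phasic spiking", "tonic bursting",
           "phasic bursting", "mixed mode", "spike frequency adaptation",
           "class 1 excitable", "class 2 excitable", "spike latency",
           "subthreshold oscillations", "resonator", "integrator",
           "rebound spike", "rebound burst", "threshold variability",
           "bistability", "DAP", "accommodation",
           "inhibition-induced spiking", "inhibition-induced bursting")
  if (extended) c(voc, "quiescent", "unclassified") else voc
}

#' Recover spike times from a stored voltage trace
#'
#' One spike per maximal run of samples at the clipped apex
#' (`v >= peak_cutoff - eps`).  Used when only the trace is available; on a
#' simulator trace it round-trips the simulator's own spike train exactly.
#'
#' @param trace a `membrane_trace`
#' @param peak_cutoff apex value; defaults to the trace's own
#' @param eps clip-detection tolerance
#' @return a [spike_train()]
#' @export
spike_times_from_trace <- function(trace, peak_cutoff = NULL, eps = 1e-9) {
  stopifnot(inherits(trace, "membrane_trace"))
  if (is.null(peak_cutoff)) peak_cutoff <- attr(trace, "peak_cutoff")
  at_peak <- trace$v >= peak_cutoff - eps
  run_start <- at_peak & !c(FALSE, at_peak[-length(at_peak)])
  spike_train(trace$times[run_start], duration_ms = max(trace$times))
}

isi_cv <- function(isi) if (length(isi) >= 2) sd(isi) / mean(isi) else NA_real_

negative_segments <- function(stimulus) {
  seg <- stimulus$segments
  seg[seg$amplitude < 0, , drop = FALSE]
}

#' Extract pattern features from a trace, spike train, and protocol
#'
#' Computes the feature set the rule-based classifier consumes: spike count,
#' latency from stimulus onset, interspike intervals, adaptation ratio
#' (last/first ISI, defined for >= 3 spikes), burst fraction (share of ISIs
#' below `burst_isi_ms`), responses relative to hyperpolarizing segments
#' (spiking during inhibition, rebound after release), probe-only responses
#' for integration/threshold protocols, and the depolarizing after-potential
#' amplitude (max voltage in the 10 ms after the last spike minus the
#' pre-stimulus baseline voltage).
#'
#' @param trace a `membrane_trace`
#' @param train a [spike_train()] on the same duration
#' @param stimulus the `stimulus_protocol` that produced the trace
#' @param burst_isi_ms ISI threshold separating burst from regular firing
#' @param rebound_window_ms window after release of inhibition in which
#'   spikes count as rebound
#' @return a list of class `pattern_features`
#' @export
extract_features <- function(trace, train, stimulus, burst_isi_ms = 10,
                             rebound_window_ms = 100) {
  stopifnot(inherits(trace, "membrane_trace"), inherits(train, "spike_train"),
            inherits(stimulus, "stimulus_protocol"))
  if (abs(max(trace$times) - train$duration_ms) > 1e-6) {
    stop("trace and spike train cover different durations", call. = FALSE)
  }
  st <- train$times_ms
  n <- length(st)
  isi <- if (n >= 2) diff(st) else numeric(0)
  seg <- stimulus$segments
  onset <- if (nrow(seg) > 0) min(seg$onset_ms) else 0

  neg <- negative_segments(stimulus)
  fired_during_inhibition <- FALSE
  n_during_inhibition <- 0L
  fired_after_release <- FALSE
  if (nrow(neg) > 0) {
    in_any <- rep(FALSE, n)
    after_any <- rep(FALSE, n)
    for (i in seq_len(nrow(neg))) {
      in_any <- in_any | (st >= neg$onset_ms[i] & st < neg$offset_ms[i])
      after_any <- after_any | (st >= neg$offset_ms[i] &
                                  st < neg$offset_ms[i] + rebound_window_ms)
    }
    fired_during_inhibition <- any(in_any)
    n_during_inhibition <- sum(in_any)
    fired_after_release <- any(after_any & !in_any)
  }

  responded_to_probe_only <- FALSE
  if (!identical(stimulus$probe, "none") && n >= 1 &&
      !is.null(stimulus$probe_window_ms)) {
    pw <- stimulus$probe_window_ms
    in_probe <- st >= pw[1] & st <= pw[2]
    in_control <- rep(FALSE, n)
    if (!is.null(stimulus$control_window_ms)) {
      cw <- stimulus$control_window_ms
      in_control <- st >= cw[1] & st <= cw[2]
    }
    responded_to_probe_only <- any(in_probe) && !any(in_control) &&
      all(in_probe | in_control)
  }

  dap_amplitude <- NA_real_
  if (n >= 1) {
    baseline_v <- mean(trace$v[trace$times < onset])
    if (!is.finite(baseline_v)) baseline_v <- trace$v[1]
    last <- st[n]
    w <- trace$times > last + 0.5 & trace$times <= last + 10
    if (any(w)) dap_amplitude <- max(trace$v[w]) - baseline_v
  }

  structure(list(
    spike_count = n,
    first_spike_latency_ms = if (n >= 1) st[1] - onset else NA_real_,
    isi_ms = isi,
    isi_cv = isi_cv(isi),
    adaptation_ratio = if (n >= 3) isi[length(isi)] / isi[1] else NA_real_,
    burst_fraction = if (length(isi) > 0) mean(isi < burst_isi_ms) else NA_real_,
    fired_during_inhibition = fired_during_inhibition,
    n_during_inhibition = n_during_inhibition,
    fired_after_release = fired_after_release,
    responded_to_probe_only = responded_to_probe_only,
    dap_amplitude = dap_amplitude,
    burst_isi_ms = burst_isi_ms
  ), class = "pattern_features")
}

#' Classification thresholds
#'
#' Tunable thresholds of the rule-based classifier; see [classify_pattern()].
#'
#' @param phasic_latency_ms max onset latency of the lone phasic spike
#' @param burst_isi_ms ISI below this is a burst interval
#' @param regular_isi_ms ISI above this counts as regular (post-burst) firing
#' @param min_burst_isis,min_regular_isis run lengths defining mixed mode
#' @param tonic_min_spikes,tonic_max_cv tonic-firing rule
#' @param inhibition_min_spikes spikes during sustained inhibition
#' @param sustained_inhibition_ms minimum width for "sustained" inhibition
#' @param dap_min_mv minimum after-potential bump (mV above baseline)
#' @return list of thresholds
#' @export
classify_thresholds <- function(phasic_latency_ms = 30, burst_isi_ms = 10,
                                regular_isi_ms = 20, min_burst_isis = 2,
                                min_regular_isis = 2, tonic_min_spikes = 4,
                                tonic_max_cv = 0.3, inhibition_min_spikes = 3,
                                sustained_inhibition_ms = 50, dap_min_mv = 2) {
  as.list(environment())
}

#' Classify a feature set into the firing-pattern vocabulary
#'
#' Deterministic ordered rule list.  A label is only reachable under its
#' probing protocol (rebound needs a hyperpolarizing pulse, the integrator
#' needs a paired-pulse probe, ...), which prevents spurious matches.
#' Rules, in order:
#' \enumerate{
#'   \item quiescent: no spikes.
#'   \item phasic spiking: exactly one spike shortly after onset of a
#'     sustained step.
#'   \item rebound spike: all spikes after release from a brief
#'     hyperpolarizing pulse.
#'   \item inhibition-induced spiking: >= 3 spikes during a sustained
#'     negative step.
#'   \item integrator / threshold variability: spikes only in the designed
#'     probe window of the matching probe protocol.
#'   \item DAP: a depolarizing after-potential bump above baseline within
#'     10 ms of the last spike, under a brief suprathreshold pulse.
#'   \item mixed mode: an initial burst (>= 2 short ISIs) followed by
#'     regular firing (>= 2 long ISIs).
#'   \item tonic spiking: sustained regular firing (>= 4 spikes, ISI CV
#'     below threshold) without a burst prefix.
#'   \item otherwise unclassified.
#' }
#'
#' @param features a `pattern_features` from [extract_features()]
#' @param stimulus the protocol the features were measured under
#' @param thresholds see [classify_thresholds()]
#' @return single character label from `pattern_vocabulary(extended = TRUE)`
#' @export
classify_pattern <- function(features, stimulus,
                             thresholds = classify_thresholds()) {
  th <- thresholds
  f <- features
  n <- f$spike_count
  if (n == 0) return("quiescent")

  if (stimulus$kind == "step" && n == 1 &&
      isTRUE(f$first_spike_latency_ms >= 0) &&
      f$first_spike_latency_ms < th$phasic_latency_ms) {
    return("phasic spiking")
  }

  neg <- negative_segments(stimulus)
  if (nrow(neg) > 0) {
    widths <- neg$offset_ms - neg$onset_ms
    brief <- any(widths <= th$sustained_inhibition_ms)
    sustained <- any(widths > th$sustained_inhibition_ms)
    if (brief && stimulus$kind %in% c("pulse", "negative_step") &&
        !f$fired_during_inhibition && f$fired_after_release) {
      return("rebound spike")
    }
    if (sustained && f$n_during_inhibition >= th$inhibition_min_spikes) {
      return("inhibition-induced spiking")
    }
  }

  if (f$responded_to_probe_only) {
    if (identical(stimulus$probe, "integrator")) return("integrator")
    if (identical(stimulus$probe, "threshold")) return("threshold variability")
  }

  if (stimulus$kind == "pulse" && nrow(neg) == 0 &&
      isTRUE(f$dap_amplitude > th$dap_min_mv)) {
    return("DAP")
  }

  isi <- f$isi_ms
  if (length(isi) >= th$min_burst_isis + th$min_regular_isis) {
    n_lead_burst <- 0L
    for (x in isi) {
      if (x < th$burst_isi_ms) n_lead_burst <- n_lead_burst + 1L else break
    }
    rest <- isi[seq_along(isi) > n_lead_burst]
    if (n_lead_burst >= th$min_burst_isis &&
        sum(rest > th$regular_isi_ms) >= th$min_regular_isis) {
      return("mixed mode")
    }
    if (n >= th$tonic_min_spikes && n_lead_burst < th$min_burst_isis &&
        isTRUE(isi_cv(isi) < th$tonic_max_cv)) {
      return("tonic spiking")
    }
  }
  "unclassified"
}

#' Classify a registry entry (or any params/protocol triple) end to end
#'
#' Convenience wrapper: simulate, extract features, classify.
#'
#' @param params,stimulus,config model, protocol, and simulation config
#' @param thresholds see [classify_thresholds()]
#' @return the label (character)
#' @export
classify_simulation <- function(params, stimulus, config,
                                thresholds = classify_thresholds()) {
  sim <- simulate_neuron(params, stimulus, config)
  f <- extract_features(sim$trace, sim$spikes, stimulus)
  classify_pattern(f, stimulus, thresholds)
}

#' Possible-pattern report matrix
#'
#' Builds a `+`/`-` matrix over the 20-pattern vocabulary: one row per
#' region, `+` where at least one of the region's clusters carries the
#' label.  Labels outside the vocabulary (e.g. `quiescent`) are ignored.
#'
#' @param labels either a named list `region -> (named list cluster ->
#'   character labels)`, or a flat named list `cluster -> labels` (treated
#'   as a single region `"all"`)
#' @return data.frame with a `region` column and one `+`/`-` column per
#'   vocabulary pattern
#' @export
pattern_table <- function(labels) {
  voc <- pattern_vocabulary()
  if (length(labels) > 0 && !is.list(labels[[1]])) {
    labels <- list(all = labels)
  }
  rows <- lapply(names(labels), function(region) {
    present <- unique(unlist(labels[[region]], use.names = FALSE))
    marks <- ifelse(voc %in% present, "+", "-")
    df <- as.data.frame(as.list(marks), check.names = FALSE)
    names(df) <- voc
    cbind(data.frame(region = region), df)
  })
  if (length(rows) == 0) {
    df <- as.data.frame(as.list(rep("-", length(voc))), check.names = FALSE)
    names(df) <- voc
    return(cbind(data.frame(region = character(0)), df[0, , drop = FALSE]))
  }
  do.call(rbind, rows)
}
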
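#' Extracellular recording container
#'
#' Single-channel voltage series with its sampling rate and optional
#' per-unit ground truth (spike times and waveform template), as produced
#' by [make_extracellular()].
#'
#' @param signal voltage series (uV)
#' @param fs_hz sampling rate (Hz), default 50000
#' @param ground_truth optional named list `unit -> list(times_ms, template)`
#' @return an `extracellular_recording`
#' @export
extracellular_recording <- function(signal, fs_hz = 50000,
                                    ground_truth = NULL) {
  structure(list(signal = as.numeric(signal), fs_hz = fs_hz,
                 duration_s = length(signal) / fs_hz,
                 ground_truth = ground_truth),
            class = "extracellular_recording")
}

#' @export
print.extracellular_recording <- function(x, ...) {
  cat(sprintf("<extracellular_recording> %.1f s at %g kHz (%d samples)%s\n",
              x$duration_s, x$fs_hz / 1000, length(x$signal),
              if (is.null(x$ground_truth)) "" else
                sprintf(", %d ground-truth units", length(x$ground_truth))))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass (the 300--10000 Hz spike band by
#' default) applied forward and backward for zero phase shift; length is
#' preserved.
#'
#' @param recording an `extracellular_recording`
#' @param low_hz,high_hz band edges; must satisfy
#'   `0 < low_hz < high_hz < fs_hz / 2`
#' @return a filtered `extracellular_recording` (ground truth carried over)
#' @export
bandpass_filter <- function(recording, low_hz = 300, high_hz = 10000) {
  stopifnot(inherits(recording, "extracellular_recording"))
  fs <- recording$fs_hz
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("band must satisfy 0 < low_hz < high_hz < fs/2", call. = FALSE)
  }
  bf <- signal::butter(2, c(low_hz, high_hz) / (fs / 2), type = "pass")
  x <- recording$signal
  n <- length(x)
  # odd-reflection padding absorbs the filter's start-up transients, which
  # decay on the scale of the low band edge (~fs / low_hz samples)
  np <- min(n - 1L, ceiling(3 * fs / low_hz))
  padded <- c(2 * x[1] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
  filtered <- signal::filtfilt(bf, padded)[(np + 1L):(np + n)]
  extracellular_recording(filtered, fs_hz = fs,
                          ground_truth = recording$ground_truth)
}

#' Amplitude-threshold spike detection
#'
#' One event per threshold crossing; the sign of `threshold_uv` selects the
#' polarity (negative threshold detects downward spikes).  Each event is
#' aligned on the signal extremum within `align_window_ms` of the crossing,
#' later crossings within `dead_time_ms` of an accepted event are ignored,
#' and a snippet of `pre_samples + post_samples` samples is cut around the
#' aligned extremum.  Events whose window would run off the recording are
#' dropped.
#'
#' @param recording a (typically band-passed) `extracellular_recording`
#' @param threshold_uv detection threshold (uV), nonzero; sign = polarity
#' @param pre_samples,post_samples snippet window around the extremum
#' @param dead_time_ms minimum separation between accepted events
#' @param align_window_ms search window for the extremum after a crossing
#' @param align_smooth_samples width of the running mean used when locating
#'   the extremum (the snippet itself is cut from the unsmoothed signal);
#'   suppresses sample-level alignment jitter from noise on flat troughs
#' @return a `waveform_set`: `snippets` (events x window matrix),
#'   `event_times_ms`, `pre_samples`, `post_samples`, `fs_hz`
#' @export
detect_spikes <- function(recording, threshold_uv, pre_samples = 25,
                          post_samples = 35, dead_time_ms = 1,
                          align_window_ms = 0.3, align_smooth_samples = 5) {
  stopifnot(inherits(recording, "extracellular_recording"))
  if (threshold_uv == 0) stop("threshold_uv must be nonzero", call. = FALSE)
  x <- recording$signal
  fs <- recording$fs_hz
  if (pre_samples + post_samples >= length(x)) {
    stop("snippet window does not fit within the signal", call. = FALSE)
  }
  if (threshold_uv < 0) {
    over <- x <= threshold_uv
    pick <- which.min
  } else {
    over <- x >= threshold_uv
    pick <- which.max
  }
  crossings <- which(over & !c(FALSE, over[-length(over)]))
  align_n <- max(1L, round(align_window_ms * fs / 1000))
  dead_n <- round(dead_time_ms * fs / 1000)
  xs <- if (align_smooth_samples > 1) {
    as.numeric(stats::filter(x, rep(1 / align_smooth_samples,
                                    align_smooth_samples), sides = 2))
  } else x
  xs[is.na(xs)] <- 0

  events <- integer(0)
  last_kept <- -Inf
  for (ci in crossings) {
    if (ci - last_kept <= dead_n) next
    hi <- min(ci + align_n, length(x))
    peak_i <- ci + pick(xs[ci:hi]) - 1L
    if (peak_i - pre_samples < 1L || peak_i + post_samples - 1L > length(x)) next
    events <- c(events, peak_i)
    last_kept <- peak_i
  }
  snippets <- matrix(0, nrow = length(events),
                     ncol = pre_samples + post_samples)
  for (j in seq_along(events)) {
    idx <- (events[j] - pre_samples):(events[j] + post_samples - 1L)
    snippets[j, ] <- x[idx]
  }
  structure(list(snippets = snippets,
                 event_times_ms = (events - 1L) / fs * 1000,
                 pre_samples = pre_samples, post_samples = post_samples,
                 fs_hz = fs),
            class = "waveform_set")
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf("<waveform_set> %d events, %d-sample window\n",
              nrow(x$snippets), ncol(x$snippets)))
  invisible(x)
}

#' Sorting features: principal components plus peak and valley
#'
#' Fits PCA on the snippet matrix itself and returns the first
#' `n_components` scores concatenated with each snippet's peak (max) and
#' valley (min) amplitude -- 5 columns by default.
#'
#' @param waveforms a `waveform_set` with at least 2 snippets
#' @param n_components number of principal-component scores
#' @return numeric matrix, `n_events x (n_components + 2)`, with column
#'   names `PC1..., peak, valley`
#' @export
extract_sort_features <- function(waveforms, n_components = 3) {
  stopifnot(inherits(waveforms, "waveform_set"))
  snips <- waveforms$snippets
  if (nrow(snips) < 2) {
    stop("need at least 2 snippets to extract features", call. = FALSE)
  }
  n_components <- min(n_components, ncol(snips), nrow(snips) - 1L)
  pc <- prcomp(snips, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  out <- cbind(scores,
               peak = apply(snips, 1, max),
               valley = apply(snips, 1, min))
  colnames(out) <- c(paste0("PC", seq_len(n_components)), "peak", "valley")
  out
}

#' Cluster detected events into putative units
#'
#' Centroid-based (k-means) partition of the feature matrix with a fixed
#' seed, so results are deterministic given the seed.
#'
#' @param features matrix from [extract_sort_features()]
#' @param k number of clusters, `1 <= k <= n_events`
#' @param seed RNG seed for the k-means starts
#' @return integer vector of cluster labels (1..k)
#' @export
cluster_events <- function(features, k, seed = 1) {
  if (k < 1 || k > nrow(features)) {
    stop("k must satisfy 1 <= k <= number of events", call. = FALSE)
  }
  if (k == 1) return(rep(1L, nrow(features)))
  set.seed(seed)
  km <- kmeans(features, centers = k, nstart = 10, iter.max = 100)
  as.integer(km$cluster)
}

#' Interspike-interval histogram and refractory-violation fraction
#'
#' Histogram of consecutive ISIs up to `max_ms`, and the fraction of ISIs
#' shorter than the refractory period -- the standard validity check for a
#' sorted unit (a well-isolated neuron produces almost no sub-refractory
#' intervals).
#'
#' @param train a [spike_train()]
#' @param bin_ms histogram bin width
#' @param max_ms histogram upper edge
#' @param refractory_ms refractory period for the violation count
#' @return list with `breaks_ms`, `counts`, `violation_fraction`; a train
#'   with fewer than 2 spikes gives empty counts and violation 0
#' @export
isi_histogram_and_violations <- function(train, bin_ms = 1, max_ms = 100,
                                         refractory_ms = 2) {
  stopifnot(inherits(train, "spike_train"), bin_ms > 0)
  isi <- diff(train$times_ms)
  breaks <- seq(0, max_ms, by = bin_ms)
  if (length(isi) == 0) {
    return(list(breaks_ms = breaks, counts = integer(length(breaks) - 1L),
                violation_fraction = 0))
  }
  counts <- tabulate(findInterval(isi, breaks, rightmost.closed = TRUE,
                                  left.open = TRUE) + 1L,
                     nbins = length(breaks))[-1L]
  list(breaks_ms = breaks, counts = counts,
       violation_fraction = mean(isi < refractory_ms))
}

#' Auto-/cross-correlogram of spike trains
#'
#' Histogram of pairwise time differences `target - reference` within
#' `±window_ms`.  When `target` is the same train as `reference` (or
#' omitted), self-pairs (i = i) are excluded, giving the auto-correlogram.
#' Bin edges run from `-window_ms` to `+window_ms` in steps of `bin_ms`,
#' so `2 * window_ms / bin_ms` must be a whole number.
#'
#' @param reference,target [spike_train()] objects
#' @param bin_ms bin width (ms)
#' @param window_ms half-width of the lag window (ms)
#' @return a `correlogram_result`: `bin_edges_ms`, `counts`
#' @export
correlogram <- function(reference, target = reference, bin_ms, window_ms) {
  stopifnot(inherits(reference, "spike_train"),
            inherits(target, "spike_train"), bin_ms > 0, window_ms > 0)
  nbins <- 2 * window_ms / bin_ms
  if (abs(nbins - round(nbins)) > 1e-9) {
    stop("2 * window_ms must be a whole multiple of bin_ms", call. = FALSE)
  }
  edges <- seq(-window_ms, window_ms, by = bin_ms)
  auto <- identical(reference$times_ms, target$times_ms)
  ref <- reference$times_ms
  tgt <- target$times_ms
  counts <- integer(length(edges) - 1L)
  for (i in seq_along(ref)) {
    lo <- findInterval(ref[i] - window_ms, tgt) + 1L
    hi <- findInterval(ref[i] + window_ms, tgt)
    if (hi < lo) next
    js <- lo:hi
    if (auto) js <- js[js != i]
    if (length(js) == 0) next
    d <- tgt[js] - ref[i]
    d <- d[d >= -window_ms & d <= window_ms]
    bin <- findInterval(d, edges, rightmost.closed = TRUE)
    counts <- counts + tabulate(bin, nbins = length(counts))
  }
  structure(list(bin_edges_ms = edges, counts = counts),
            class = "correlogram_result")
}

#' @export
print.correlogram_result <- function(x, ...) {
  cat(sprintf("<correlogram_result> %d bins over [%g, %g] ms, %d pairs\n",
              length(x$counts), min(x$bin_edges_ms), max(x$bin_edges_ms),
              sum(x$counts)))
  invisible(x)
}

#' Average firing-rate histogram
#'
#' Spike counts per bin divided by the bin width, in Hz, covering the full
#' recording `[0, duration]`.
#'
#' @param train a [spike_train()]
#' @param bin_s bin width in seconds
#' @return list with `breaks_s` and `rate_hz`
#' @export
firing_rate_histogram <- function(train, bin_s) {
  stopifnot(inherits(train, "spike_train"), bin_s > 0)
  dur_s <- train$duration_ms / 1000
  nbins <- max(1L, ceiling(dur_s / bin_s - 1e-12))
  breaks <- (0:nbins) * bin_s
  t_s <- train$times_ms / 1000
  idx <- pmin(findInterval(t_s, breaks, rightmost.closed = TRUE), nbins)
  counts <- tabulate(idx, nbins = nbins)
  list(breaks_s = breaks, rate_hz = counts / bin_s)
}

#' Run the full sorting chain on a recording
#'
#' Band-pass filter, threshold detection, PCA + peak/valley features,
#' k-means clustering, and per-cluster ISI validation -- the automated
#' counterpart of a manual offline-sorter workflow.  The detection
#' threshold can be given explicitly or derived as `-thr_mad_k` times the
#' MAD-based noise estimate (`median(|x|) / 0.6745`).
#'
#' @param recording raw `extracellular_recording`
#' @param k number of clusters
#' @param threshold_uv detection threshold; `NULL` = use the MAD rule
#' @param thr_mad_k multiplier for the MAD-derived threshold
#' @param seed clustering seed
#' @param refractory_ms refractory period for ISI validation
#' @param ... passed to [detect_spikes()]
#' @return a `sort_result`: `labels`, `features`, `event_times_ms`,
#'   `trains` (per-cluster [spike_train()]s), `isi_violation_fraction`
#'   (per cluster), `threshold_uv`, `waveforms`
#' @export
sort_recording <- function(recording, k, threshold_uv = NULL, thr_mad_k = 4.5,
                           seed = 1, refractory_ms = 2, ...) {
  filtered <- bandpass_filter(recording)
  if (is.null(threshold_uv)) {
    noise_sd <- median(abs(filtered$signal)) / 0.6745
    threshold_uv <- -thr_mad_k * noise_sd
  }
  wf <- detect_spikes(filtered, threshold_uv, ...)
  feats <- extract_sort_features(wf)
  labels <- cluster_events(feats, k = k, seed = seed)
  dur_ms <- recording$duration_s * 1000
  trains <- lapply(sort(unique(labels)), function(cl) {
    spike_train(sort(wf$event_times_ms[labels == cl]), duration_ms = dur_ms)
  })
  names(trains) <- paste0("cluster_", sort(unique(labels)))
  viol <- vapply(trains, function(tr) {
    isi_histogram_and_violations(tr, refractory_ms = refractory_ms)$violation_fraction
  }, numeric(1))
  structure(list(labels = labels, features = feats,
                 event_times_ms = wf$event_times_ms, trains = trains,
                 isi_violation_fraction = viol, threshold_uv = threshold_uv,
                 waveforms = wf),
            class = "sort_result")
}

#' @export
print.sort_result <- function(x, ...) {
  cat(sprintf("<sort_result> %d events in %d clusters (threshold %.1f uV)\n",
              length(x$labels), length(x$trains), x$threshold_uv))
  invisible(x)
}

#' Score a sort against ground truth
#'
#' Matches detected events to true spike times within `tol_ms`, computes
#' detection recall, and the cluster-assignment accuracy under the optimal
#' cluster-to-unit permutation (evaluated over matched events).
#'
#' @param result a `sort_result`
#' @param recording the `extracellular_recording` carrying `ground_truth`
#' @param tol_ms matching tolerance (ms)
#' @return list with `recall`, `accuracy`, `n_true`, `n_detected`,
#'   `permutation`
#' @export
score_sort <- function(result, recording, tol_ms = 0.5) {
  gt <- recording$ground_truth
  if (is.null(gt)) stop("recording has no ground truth", call. = FALSE)
  true_times <- unlist(lapply(gt, `[[`, "times_ms"), use.names = FALSE)
  true_unit <- rep(seq_along(gt), vapply(gt, function(g) length(g$times_ms),
                                         integer(1)))
  ord <- order(true_times)
  true_times <- true_times[ord]
  true_unit <- true_unit[ord]
  det <- result$event_times_ms

  # greedy nearest matching of each true spike to an unused detected event
  matched_det <- rep(NA_integer_, length(true_times))
  used <- rep(FALSE, length(det))
  for (i in seq_along(true_times)) {
    cand <- which(!used & abs(det - true_times[i]) <= tol_ms)
    if (length(cand) > 0) {
      j <- cand[which.min(abs(det[cand] - true_times[i]))]
      matched_det[i] <- j
      used[j] <- TRUE
    }
  }
  hit <- !is.na(matched_det)
  recall <- mean(hit)

  k <- length(result$trains)
  n_units <- length(gt)
  lab <- result$labels[matched_det[hit]]
  tru <- true_unit[hit]
  perms <- all_permutations(seq_len(max(k, n_units)))
  best <- 0
  best_perm <- perms[[1]]
  for (p in perms) {
    acc <- mean(p[tru] == lab)
    if (!is.na(acc) && acc > best) {
      best <- acc
      best_perm <- p
    }
  }
  list(recall = recall, accuracy = best, n_true = length(true_times),
       n_detected = length(det), permutation = best_perm)
}

all_permutations <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in all_permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  }
  out
}
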
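test_that("band-pass filter rejects DC and 50 Hz but passes 1 kHz", {
  fs <- 50000
  t <- seq(0, 1, by = 1 / fs)[-1]

  dc <- extracellular_recording(rep(100, length(t)), fs)
  expect_lt(max(abs(bandpass_filter(dc)$signal)), 100 * 1e-6)

  mid <- function(x) x[5001:(length(x) - 5000)]
  pass <- extracellular_recording(sin(2 * pi * 1000 * t), fs)
  expect_equal(max(abs(mid(bandpass_filter(pass)$signal))), 1,
               tolerance = 0.05)

  hum <- extracellular_recording(sin(2 * pi * 50 * t), fs)
  expect_lt(max(abs(mid(bandpass_filter(hum)$signal))), 0.05)

  expect_error(bandpass_filter(pass, low_hz = 300, high_hz = 30000), "band")
})

test_that("threshold detection finds an inserted template once", {
  fs <- 50000
  tpl <- biphasic_template(fs) * 100   # 100 uV valley depth
  x <- numeric(fs)                     # 1 s of silence
  ins <- 25000
  x[ins:(ins + length(tpl) - 1)] <- tpl
  rec <- extracellular_recording(x, fs)

  wf <- detect_spikes(rec, threshold_uv = -50)
  expect_identical(nrow(wf$snippets), 1L)
  valley_ms <- (ins - 1 + which.min(tpl) - 1) / fs * 1000
  expect_lt(abs(wf$event_times_ms[1] - valley_ms), 0.1)

  expect_identical(nrow(detect_spikes(rec, threshold_uv = -150)$snippets), 0L)
})

test_that("detection counts all well-separated events at SNR 10", {
  fs <- 50000
  tpl <- biphasic_template(fs) * 100
  x <- numeric(5 * fs)
  starts <- seq(1000, length(x) - length(tpl), length.out = 100)
  for (s in round(starts)) x[s:(s + length(tpl) - 1)] <- x[s:(s + length(tpl) - 1)] + tpl
  set.seed(99)
  x <- x + rnorm(length(x), 0, 10)
  wf <- detect_spikes(extracellular_recording(x, fs), threshold_uv = -50)
  expect_identical(nrow(wf$snippets), 100L)
})

test_that("sort features are PCA scores plus peak and valley", {
  fs <- 50000
  tpl <- biphasic_template(fs) * 100
  same <- matrix(rep(tpl, 10), nrow = 10, byrow = TRUE)
  wf <- structure(list(snippets = same, event_times_ms = 1:10,
                       pre_samples = 10, post_samples = 50, fs_hz = fs),
                  class = "waveform_set")
  f <- extract_sort_features(wf)
  expect_lt(max(abs(f[, 1:3])), 1e-8)          # zero variance -> zero scores
  expect_equal(f[, "peak"], apply(same, 1, max))
  expect_equal(f[, "valley"], apply(same, 1, min))

  # two distinct populations separate on PC1 with no overlap
  tpl2 <- biphasic_template(fs, width_ms = 1.2)
  tpl2 <- rev(tpl2) * 100
  set.seed(7)
  pop <- rbind(t(replicate(20, tpl + rnorm(length(tpl), 0, 10))),
               t(replicate(20, tpl2 + rnorm(length(tpl), 0, 10))))
  wf2 <- structure(list(snippets = pop, event_times_ms = 1:40,
                        pre_samples = 10, post_samples = 50, fs_hz = fs),
                   class = "waveform_set")
  s <- extract_sort_features(wf2)[, 1]
  expect_true(max(s[21:40]) < min(s[1:20]) || max(s[1:20]) < min(s[21:40]))

  one <- structure(list(snippets = same[1, , drop = FALSE],
                        event_times_ms = 1, pre_samples = 10,
                        post_samples = 50, fs_hz = fs),
                   class = "waveform_set")
  expect_error(extract_sort_features(one), "at least 2")
})

test_that("k-means clustering separates distinct feature blobs", {
  set.seed(3)
  blobs <- rbind(matrix(rnorm(100, 0, 1), ncol = 2),
                 matrix(rnorm(100, 10, 1), ncol = 2))
  labels <- cluster_events(blobs, k = 2, seed = 5)
  expect_identical(length(unique(labels[1:50])), 1L)
  expect_identical(length(unique(labels[51:100])), 1L)
  expect_false(labels[1] == labels[51])

  expect_identical(cluster_events(blobs, k = 1), rep(1L, 100))
  expect_error(cluster_events(blobs, k = 101), "k must")
  expect_identical(cluster_events(blobs, k = 2, seed = 5),
                   cluster_events(blobs, k = 2, seed = 5))
})

test_that("ISI histogram counts intervals and refractory violations", {
  tr <- spike_train(c(0, 10, 20, 30), 100)
  h <- isi_histogram_and_violations(tr, bin_ms = 1, max_ms = 50)
  expect_identical(sum(h$counts), 3L)
  expect_identical(h$counts[10], 3L)  # all ISIs in the (9, 10] bin
  expect_identical(h$violation_fraction, 0)

  h2 <- isi_histogram_and_violations(spike_train(c(0, 1, 10), 100))
  expect_equal(h2$violation_fraction, 0.5)

  h0 <- isi_histogram_and_violations(spike_train(numeric(0), 100))
  expect_identical(sum(h0$counts), 0L)
  expect_identical(h0$violation_fraction, 0)
})

test_that("correlogram matches the hand-worked auto-correlogram example", {
  tr <- spike_train(c(10, 20, 30), 100)
  cg <- correlogram(tr, bin_ms = 5, window_ms = 12.5)
  expect_equal(cg$counts, c(2L, 0L, 0L, 0L, 2L))
  expect_equal(cg$counts, rev(cg$counts))  # pair symmetry
})

test_that("cross-correlogram of a shifted copy peaks at the shift", {
  base <- seq(0, 900, by = 100)
  a <- spike_train(base, 1000)
  b <- spike_train(base + 5, 1000)
  cg <- correlogram(a, b, bin_ms = 2, window_ms = 10)
  peak_bin <- which(cg$counts == max(cg$counts))
  centers <- cg$bin_edges_ms[-1] - 1
  expect_equal(centers[peak_bin], 5)
  expect_identical(max(cg$counts), length(base))
  expect_identical(sum(cg$counts), length(base))
})

test_that("correlogram equals brute-force pair enumeration on random trains", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:120, 1)
    t1 <- sort(runif(n, 0, 500))
    t2 <- sort(runif(sample(5:120, 1), 0, 500))
    tr1 <- spike_train(t1, 500)
    tr2 <- spike_train(t2, 500)
    expect_identical(correlogram(tr1, bin_ms = 5, window_ms = 50)$counts,
                     brute_correlogram(t1, t1, 5, 50, auto = TRUE))
    expect_identical(correlogram(tr1, tr2, bin_ms = 5, window_ms = 50)$counts,
                     brute_correlogram(t1, t2, 5, 50, auto = FALSE))
  }
})

test_that("firing-rate histogram covers the recording and conserves counts", {
  tr <- spike_train(0:29 * 1000, 30000)  # 30 spikes, 1 s apart
  h <- firing_rate_histogram(tr, bin_s = 1)
  expect_equal(h$rate_hz, rep(1, 30))

  h0 <- firing_rate_histogram(spike_train(numeric(0), 30000), 1)
  expect_equal(h0$rate_hz, rep(0, 30))

  pois <- make_poisson_train(5, 120, refractory_ms = 2, seed = 8)
  hp <- firing_rate_histogram(pois, bin_s = 2)
  expect_identical(sum(hp$rate_hz * 2), as.numeric(length(pois$times_ms)))
})

test_that("the full sorting chain recovers a short 3-unit recording", {
  rec <- standard_recording(seed = 2024, duration_s = 15)
  sorted <- sort_recording(rec, k = 3, seed = 1)
  sc <- score_sort(sorted, rec)
  expect_gte(sc$recall, 0.9)
  expect_gte(sc$accuracy, 0.9)
  expect_true(all(sorted$isi_violation_fraction < 0.02))
})
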
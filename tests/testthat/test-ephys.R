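test_that("the PSTH has the printed bin layout and exact counts", {
  r <- spike_raster(1, 1002, n_neurons = 1, duration = 2000)
  p <- psth(r, stim_times = 1)
  # (-100, +400) ms at 4 ms -> 125 bins
  expect_length(p$pooled, 125)
  expect_equal(sum(p$pooled), 1)
  expect_equal(p$pooled[which(p$mids == 2)], 1)
  # a pre-stimulus spike lands in the negative limb
  r2 <- spike_raster(c(1, 2), c(950, 1399.9), 2, 2000)
  p2 <- psth(r2, 1)
  expect_equal(sum(p2$counts[1, p2$mids < 0]), 1)
  expect_equal(sum(p2$counts[2, ]), 1)
  expect_equal(p2$pooled, colSums(p2$counts))
  expect_error(psth(r, numeric(0)), "one stimulus")
  expect_error(psth(r, 1, bin_ms = 3), "whole number")
})

test_that("PSTH counts are conserved over the analysis window", {
  set.seed(61)
  r <- spike_raster(sample.int(4, 500, TRUE), runif(500, 0, 60000), 4, 60000)
  stims <- seq(5, 50, by = 5)
  p <- psth(r, stims)
  manual <- sum(vapply(stims * 1000, function(s)
    sum(r$time >= s - 100 & r$time < s + 400), 0))
  expect_equal(sum(p$pooled), manual)
})

test_that("Poisson spiking produces a flat PSTH", {
  flat <- vapply(1:10, function(s) {
    set.seed(700 + s)
    r <- spike_raster(sample.int(8, 6000, TRUE), runif(6000, 0, 300000),
                      8, 300000)
    p <- psth(r, seq(10, 290, by = 20))
    suppressWarnings(stats::chisq.test(p$pooled)$p.value) > 0.05
  }, TRUE)
  expect_gte(mean(flat), 0.9)
})

test_that("evoked counts report exact means on constructed rasters", {
  stims <- c(10, 30, 50)
  # exactly 3 spikes 20-180 ms after pulse 1, one spike after pulse 2
  t1 <- unlist(lapply(stims * 1000, function(s) s + c(20, 90, 180)))
  t2 <- stims * 1000 + 200 + 50
  r <- spike_raster(rep(1, length(t1) + length(t2)), c(t1, t2), 1, 60000)
  ec <- evoked_count(r, stimulus_protocol(stims))
  expect_equal(ec$counts1, c(3, 3, 3))
  expect_equal(ec$mean1, 3)
  expect_equal(ec$sem1, 0)
  expect_equal(ec$mean2, 1)
  # empty raster -> zero everywhere
  r0 <- spike_raster(integer(0), numeric(0), 1, 60000)
  expect_equal(evoked_count(r0, stimulus_protocol(stims))$mean1, 0)
})

test_that("evoked counts are additive over disjoint raster unions", {
  stims <- stimulus_protocol(c(5, 15))
  ra <- spike_raster(rep(1, 4), c(5050, 5100, 15020, 15120), 1, 30000)
  rb <- spike_raster(rep(1, 2), c(5150, 15090), 1, 30000)
  runion <- spike_raster(rep(1, 6), sort(c(ra$time, rb$time)), 1, 30000)
  ca <- evoked_count(ra, stims)$counts1
  cb <- evoked_count(rb, stims)$counts1
  cu <- evoked_count(runion, stims)$counts1
  expect_equal(cu, ca + cb)
})

test_that("removing evoked spikes is detected by the rank-sum comparison", {
  set.seed(19)
  stims <- seq(10, 200, by = 20)
  # pre: strong evoked response after each pulse; post: responses removed
  evoked <- unlist(lapply(stims * 1000, function(s) s + runif(8, 5, 180)))
  background <- runif(200, 0, 210000)
  pre <- spike_raster(rep(1, length(evoked) + 200),
                      sort(c(evoked, background)), 1, 210000)
  post <- spike_raster(rep(1, 200), sort(background), 1, 210000)
  c_pre <- evoked_count(pre, stimulus_protocol(stims, ipi_ms = NA))$counts1
  c_post <- evoked_count(post, stimulus_protocol(stims, ipi_ms = NA))$counts1
  p <- suppressWarnings(wilcox.test(c_pre, c_post)$p.value)
  expect_lt(p, 0.05)
})

test_that("overlapping paired-pulse windows are truncated with a warning", {
  r <- spike_raster(1, 10150, 1, 30000)
  expect_warning(
    ec <- evoked_count(r, stimulus_protocol(10, ipi_ms = 100), window_ms = 200),
    "truncated")
  expect_equal(ec$counts2, 1)  # the spike at +150 ms belongs to pulse 2
  expect_equal(ec$counts1, 0)
})

test_that("the SWT detector is silent on flat input and gain-invariant", {
  flat <- swt_detect(rep(2.5, 30000), fs = 25000)
  expect_length(flat, 0)
  expect_true(attr(flat, "degenerate"))
  st <- synthetic_ephys_trace(3, fs = 25000, snr = 8, seed = 12)
  d1 <- swt_detect(st$signal, st$fs)
  d2 <- swt_detect(7.5 * st$signal, st$fs)
  expect_equal(d1, d2)
})

test_that("the SWT detector meets its benchmark recall and FP budget", {
  stats <- vapply(1:10, function(s) {
    st <- synthetic_ephys_trace(10, fs = 25000, snr = 8, seed = s)
    det <- swt_detect(st$signal, st$fs)
    m <- match_events(st$spike_times, det, tol = 0.002)
    c(true = length(st$spike_times), det = length(det), tp = m$tp)
  }, numeric(3))
  recall <- sum(stats["tp", ]) / sum(stats["true", ])
  fp_per_min <- sum(stats["det", ] - stats["tp", ]) / (100 / 60)
  expect_gte(recall, 0.95)
  expect_lte(fp_per_min, 1)
})

test_that("detections commute with circular shifts away from boundaries", {
  st <- synthetic_ephys_trace(4, fs = 25000, snr = 8, seed = 21)
  x <- st$signal
  k <- 12345
  xs <- c(x[(k + 1):length(x)], x[1:k])
  d0 <- swt_detect(x, st$fs)
  ds <- swt_detect(xs, st$fs)
  # compare events living at least 0.1 s away from either boundary
  interior <- d0[d0 > k / 25000 + 0.1 & d0 < 4 - 0.1]
  mapped <- ds[ds > 0.1 & ds < 4 - k / 25000 - 0.1] + k / 25000
  m <- match_events(interior, mapped, tol = 0.002)
  expect_gte(m$tp / length(interior), 0.95)
})

test_that("fixed-point and floating detections agree at benchmark SNR", {
  agree <- vapply(1:5, function(s) {
    st <- synthetic_ephys_trace(10, fs = 25000, snr = 8, seed = 30 + s)
    a <- swt_detect(st$signal, st$fs)
    b <- swt_detect(st$signal, st$fs, fixed_point = TRUE)
    m <- match_events(a, b, tol = 0.001)
    m$tp / max(length(a), length(b))
  }, 0)
  expect_gte(mean(agree), 0.99)
})

test_that("the band-pass helpers preserve band-limited content", {
  fs <- 12500
  tt <- seq(0, 1, by = 1 / fs)
  x <- sin(2 * pi * 1500 * tt) + sin(2 * pi * 20 * tt)
  mua <- bandpass_mua(x, fs)
  lfp <- bandpass_lfp(x, fs)
  mid <- 2000:10000
  # each band keeps its own component and rejects the other
  expect_lt(max(abs(mua[mid] - sin(2 * pi * 1500 * tt)[mid])), 0.05)
  expect_lt(max(abs(lfp[mid] - sin(2 * pi * 20 * tt)[mid])), 0.05)
})
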
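#' Stimulation protocol
#'
#' @param times pulse-1 onset times (s), increasing.
#' @param ipi_ms paired-pulse inter-pulse interval (ms); `NA` for single
#'   pulses. Default 200.
#' @param rate_hz nominal delivery rate (Hz), metadata only (default 0.05).
#' @return list of class `"stimulus_protocol"`.
#' @export
stimulus_protocol <- function(times, ipi_ms = 200, rate_hz = 0.05) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) stopf("`times` must be increasing")
  if (!is.na(ipi_ms) && ipi_ms <= 0) stopf("`ipi_ms` must be positive")
  structure(list(times = times, ipi_ms = ipi_ms, rate_hz = rate_hz),
            class = "stimulus_protocol")
}

#' Peri-stimulus time histogram
#'
#' Spike counts in fixed bins relative to each stimulus onset, per channel
#' and pooled over the array. The conventional configuration -- 4-ms bins
#' over (-100, +400) ms -- yields 125 bins.
#'
#' @param raster a [spike_raster()] (times in ms; "neuron" doubles as the
#'   recording channel).
#' @param stim_times stimulus onsets in seconds (a numeric vector or a
#'   [stimulus_protocol()], in which case both pulses of each pair are used).
#' @param bin_ms bin width (ms, default 4).
#' @param window c(before, after) window relative to the stimulus (ms,
#'   default c(-100, 400)); must span a whole number of bins.
#' @return object of class `"psth_result"`: list with `edges` (bin edges,
#'   ms), `mids`, `counts` (channels x bins matrix), `pooled` (bin sums over
#'   channels), `n_stimuli`.
#' @examples
#' r <- spike_raster(1, 1002, n_neurons = 1, duration = 2000)
#' p <- psth(r, stim_times = 1)
#' p$pooled[p$mids == 2]  # the spike lands in the first post-stimulus bin
#' @export
psth <- function(raster, stim_times, bin_ms = 4, window = c(-100, 400)) {
  if (inherits(stim_times, "stimulus_protocol")) {
    pr <- stim_times
    stim_times <- pr$times
    if (!is.na(pr$ipi_ms)) stim_times <- sort(c(stim_times,
                                                stim_times + pr$ipi_ms / 1000))
  }
  if (!length(stim_times)) stopf("need at least one stimulus")
  span <- diff(window)
  if (abs(span / bin_ms - round(span / bin_ms)) > 1e-9)
    stopf("window must span a whole number of bins")
  n_bins <- round(span / bin_ms)
  edges <- window[1] + bin_ms * (0:n_bins)
  n_ch <- attr(raster, "n_neurons")
  counts <- matrix(0L, n_ch, n_bins)
  stim_ms <- stim_times * 1000
  for (s in stim_ms) {
    rel <- raster$time - s
    sel <- rel >= window[1] & rel < window[2]
    if (!any(sel)) next
    b <- floor((rel[sel] - window[1]) / bin_ms) + 1L
    for (q in seq_along(b))
      counts[raster$neuron[sel][q], b[q]] <- counts[raster$neuron[sel][q], b[q]] + 1L
  }
  structure(list(edges = edges, mids = edges[-1] - bin_ms / 2,
                 counts = counts, pooled = colSums(counts),
                 n_stimuli = length(stim_ms), bin_ms = bin_ms,
                 window = window),
            class = "psth_result")
}

#' @export
print.psth_result <- function(x, ...) {
  cat(sprintf("<psth_result> %d bins of %g ms over (%g, %g) ms, %d stimuli, %d spikes\n",
              length(x$pooled), x$bin_ms, x$window[1], x$window[2],
              x$n_stimuli, sum(x$pooled)))
  invisible(x)
}

#' @export
plot.psth_result <- function(x, ...) {
  graphics::barplot(x$pooled, names.arg = round(x$mids), space = 0,
                    xlab = "time from stimulus (ms)", ylab = "spike count",
                    ...)
  invisible(x)
}

#' Evoked spike counts after each stimulus pulse
#'
#' Counts spikes (pooled over channels) in the `(0, window_ms]` interval
#' after every pulse; for paired-pulse protocols, pulse-1 and pulse-2 counts
#' are reported separately together with a Mann-Whitney rank-sum comparison
#' of the two. Windows longer than the inter-pulse interval are truncated at
#' the next pulse with a warning.
#'
#' @param raster a [spike_raster()].
#' @param protocol a [stimulus_protocol()].
#' @param window_ms response window (ms, default 200).
#' @return object of class `"evoked_count"`: list with per-stimulus count
#'   vectors `counts1`, `counts2` (NULL if single-pulse), their means and
#'   SEMs, and `p_rank_sum` comparing the two pulses.
#' @export
evoked_count <- function(raster, protocol, window_ms = 200) {
  if (!inherits(protocol, "stimulus_protocol"))
    protocol <- stimulus_protocol(protocol)
  if (!length(protocol$times)) stopf("need at least one stimulus")
  paired <- !is.na(protocol$ipi_ms)
  win1 <- window_ms
  if (paired && window_ms > protocol$ipi_ms) {
    warning("response window overlaps the second pulse; truncated",
            call. = FALSE)
    win1 <- protocol$ipi_ms
  }
  count_after <- function(t0_ms, win)
    sum(raster$time > t0_ms & raster$time <= t0_ms + win)
  t1 <- protocol$times * 1000
  counts1 <- vapply(t1, count_after, 0, win = win1)
  counts2 <- NULL
  p <- NA_real_
  if (paired) {
    counts2 <- vapply(t1 + protocol$ipi_ms, count_after, 0, win = window_ms)
    p <- tryCatch(suppressWarnings(
      wilcox.test(counts1, counts2)$p.value), error = function(e) NA_real_)
  }
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  structure(list(counts1 = counts1, counts2 = counts2,
                 mean1 = mean(counts1), sem1 = sem(counts1),
                 mean2 = if (paired) mean(counts2) else NA_real_,
                 sem2 = if (paired) sem(counts2) else NA_real_,
                 p_rank_sum = p, window_ms = window_ms),
            class = "evoked_count")
}

#' @export
print.evoked_count <- function(x, ...) {
  cat(sprintf("<evoked_count> pulse 1: %.2f +/- %.2f spikes / stimulus\n",
              x$mean1, x$sem1))
  if (!is.null(x$counts2))
    cat(sprintf("  pulse 2: %.2f +/- %.2f (rank-sum p = %.3g)\n",
                x$mean2, x$sem2, x$p_rank_sum))
  invisible(x)
}

# -- stationary wavelet transform -------------------------------------------

# Undecimated (a trous) Haar decomposition. At level j the filter taps sit
# 2^(j-1) samples apart:
#   a_j[t] = (a_{j-1}[t] + a_{j-1}[t + s]) / sqrt(2)
#   d_j[t] = (a_{j-1}[t] - a_{j-1}[t + s]) / sqrt(2),  s = 2^(j-1)
# with symmetric (reflecting) padding at the right boundary.
swt_haar <- function(x, levels, quantize = NULL) {
  n <- length(x)
  details <- vector("list", levels)
  a <- x
  if (!is.null(quantize)) a <- quantize(a)
  for (j in seq_len(levels)) {
    s <- 2L^(j - 1L)
    idx <- seq_len(n) + s
    over <- idx > n
    idx[over] <- 2L * n - idx[over] + 1L   # reflect
    shifted <- a[idx]
    d <- (a - shifted) / sqrt(2)
    a <- (a + shifted) / sqrt(2)
    if (!is.null(quantize)) { d <- quantize(d); a <- quantize(a) }
    details[[j]] <- d
  }
  list(details = details, approx = a)
}

#' Stationary-wavelet-transform spike detector
#'
#' Software reference of a hardware spike detector: the trace is decomposed
#' with an undecimated Haar wavelet transform; detections are samples where
#' the absolute level-`signal_level` detail coefficient exceeds `k` times
#' the standard deviation of the level-`noise_level` detail, the SD being
#' estimated block-wise over `block_s`-second windows. Threshold crossings
#' within one filter support (`2^signal_level` samples) belong to the same
#' event, timed at the largest detail coefficient plus half the support;
#' events closer than the refractory period are then merged. The optional
#' 16-bit fixed-point mode rounds the input and every wavelet coefficient to
#' a signed 16-bit grid scaled to the signal range, emulating hardware
#' quantization.
#'
#' The default `k = 5.5` was calibrated on the synthetic biphasic-template
#' benchmark ([synthetic_ephys_trace()]): it sits mid-way along the plateau
#' where recall stays 1 and false positives stay 0 at peak SNR 8.
#'
#' @param signal numeric voltage trace.
#' @param fs sampling rate (Hz).
#' @param k threshold multiplier (default 5.5).
#' @param signal_level detail level carrying the spike band (default 6).
#' @param noise_level detail level used for the noise SD (default 1).
#' @param refractory_ms merge window (ms, default 1).
#' @param block_s block length for the noise SD (s, default 1).
#' @param fixed_point use 16-bit fixed-point arithmetic (default FALSE).
#' @return numeric vector of detection times (s); attribute
#'   `degenerate = TRUE` when the noise SD was zero (flat input).
#' @examples
#' syn <- synthetic_ephys_trace(2, fs = 25000, snr = 8, seed = 1)
#' length(swt_detect(syn$signal, syn$fs)) >= length(syn$spike_times) * 0.9
#' @export
swt_detect <- function(signal, fs, k = 5.5, signal_level = 6, noise_level = 1,
                       refractory_ms = 1, block_s = 1, fixed_point = FALSE) {
  if (signal_level <= noise_level || noise_level < 1)
    stopf("need signal_level > noise_level >= 1")
  if (k <= 0) stopf("`k` must be positive")
  n <- length(signal)
  if (n < 2^signal_level) stopf("signal shorter than 2^signal_level samples")
  quantize <- NULL
  if (fixed_point) {
    # full-scale chosen so coefficients (growing by sqrt(2) per level) fit
    rng <- max(abs(signal))
    if (rng == 0) rng <- 1
    q <- 32767 / (rng * 2^((signal_level + 1) / 2))
    quantize <- function(v) pmin(pmax(round(v * q), -32768), 32767) / q
  }
  dec <- swt_haar(signal, signal_level, quantize)
  d_sig <- abs(dec$details[[signal_level]])
  d_noise <- dec$details[[noise_level]]
  block <- max(1L, round(block_s * fs))
  starts <- seq(1L, n, by = block)
  above <- logical(n)
  degenerate <- TRUE
  for (s0 in starts) {
    s1 <- min(n, s0 + block - 1L)
    sdv <- sd(d_noise[s0:s1])
    if (is.na(sdv) || sdv == 0) next
    degenerate <- FALSE
    above[s0:s1] <- d_sig[s0:s1] > k * sdv
  }
  idx <- which(above)
  if (!length(idx))
    return(structure(numeric(0), degenerate = degenerate))
  support <- 2L^signal_level
  grp <- cumsum(c(TRUE, diff(idx) > support))
  peaks <- vapply(split(idx, grp), function(ii) ii[which.max(d_sig[ii])], 0)
  times <- (peaks + support / 2) / fs
  refr <- refractory_ms / 1000
  keep <- c(TRUE, diff(times) > refr)
  structure(unname(times[keep]), degenerate = FALSE)
}

#' Zero-phase band-pass filters for extracellular traces
#'
#' Convenience preprocessing: Butterworth filters applied forward and
#' backward ([signal::filtfilt()]), selecting the multi-unit activity band
#' (800 Hz - 3 kHz) or the local-field-potential band (1 - 300 Hz). The LFP
#' band is realized as a low-pass / high-pass cascade: a single band-pass
#' with a 1-Hz lower edge is numerically ill-conditioned at typical
#' extracellular sampling rates.
#'
#' @param x voltage trace.
#' @param fs sampling rate (Hz).
#' @return filtered trace.
#' @export
bandpass_mua <- function(x, fs) {
  bf <- signal::butter(4, c(800, 3000) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' @rdname bandpass_mua
#' @export
bandpass_lfp <- function(x, fs) {
  lp <- signal::butter(4, 300 / (fs / 2), type = "low")
  hp <- signal::butter(2, 1 / (fs / 2), type = "high")
  signal::filtfilt(hp, signal::filtfilt(lp, x))
}
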
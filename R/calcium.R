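#' Fluorescence recording container
#'
#' @param F numeric matrix, neurons x frames (arbitrary fluorescence units).
#' @param frame_rate acquisition rate in Hz (default 59).
#' @param gaba optional logical flag per neuron (GABAergic identity).
#' @return matrix of class `"fluorescence_recording"` with attributes
#'   `frame_rate` and `gaba`.
#' @export
fluorescence_recording <- function(F, frame_rate = 59, gaba = NULL) {
  F <- as.matrix(F)
  if (frame_rate <= 0) stopf("`frame_rate` must be positive")
  if (ncol(F) <= frame_rate)
    stopf("recording must be longer than 1 s (> %d frames)", ceiling(frame_rate))
  if (!is.null(gaba) && length(gaba) != nrow(F))
    stopf("`gaba` must have one flag per neuron")
  attr(F, "frame_rate") <- frame_rate
  attr(F, "gaba") <- gaba
  class(F) <- c("fluorescence_recording", class(F))
  F
}

#' @export
print.fluorescence_recording <- function(x, ...) {
  cat(sprintf("<fluorescence_recording> %d neurons x %d frames at %g Hz (%.1f s)\n",
              nrow(x), ncol(x), attr(x, "frame_rate"),
              ncol(x) / attr(x, "frame_rate")))
  invisible(x)
}

#' First-difference + 1-s sliding-window integration of fluorescence traces
#'
#' For each neuron the trace is differenced (`dF[j] = F[j+1] - F[j]`) and the
#' differences are summed over overlapping sliding windows of 1 s
#' (`window = round(frame_rate)` frames), yielding the processed signal
#' `I[j'] = sum(dF[j' .. j'+window-1])`, `j' = 1 .. N - window`. By
#' telescoping this equals `F[j'+window] - F[j']`, so the construction is
#' exactly invariant to any constant baseline shift.
#'
#' @param rec a [fluorescence_recording()].
#' @return object of class `"processed_signal"`: list with `I` (neurons x
#'   `N - window` matrix), `window` (frames), `frame_rate`.
#' @export
process_traces <- function(rec) {
  fr <- attr(rec, "frame_rate")
  window <- round(fr)
  N <- ncol(rec)
  if (N < window + 2) stopf("recording too short for a 1-s window")
  n_out <- N - window
  idx <- seq_len(n_out)
  I <- rec[, idx + window, drop = FALSE] - rec[, idx, drop = FALSE]
  structure(list(I = unclass(I), window = window, frame_rate = fr),
            class = "processed_signal")
}

#' Estimate the noise SD of a processed signal by a zero-centered Gaussian fit
#'
#' Least-squares fit of a zero-mean Gaussian bell (plus a flat pedestal that
#' absorbs event contamination) to the histogram of the signal's noise core.
#' The core is located robustly: an initial scale is taken as the lower
#' quartile of per-segment SDs (event-free stretches dominate the low
#' quartile), the histogram is built over values within 4 initial scales of
#' zero with a Freedman-Diaconis bin width, and `A exp(-x^2/(2 sigma^2)) + C`
#' is fitted to the bin counts. Every step scales linearly, so the estimate
#' is exactly equivariant under positive rescaling of the input.
#'
#' @param I_row numeric vector (one neuron's processed signal), >= 200
#'   samples.
#' @param segment segment length (samples) for the initial scale; defaults
#'   to one 1-s integration window (59).
#' @return the estimated `sigma` (>= 0), with attribute `degenerate = TRUE`
#'   when the signal is constant (sigma 0).
#' @export
estimate_noise_sigma <- function(I_row, segment = 59) {
  if (length(I_row) < 200) stopf("need at least 200 samples")
  if (sd(I_row) == 0)
    return(structure(0, degenerate = TRUE))
  ns <- max(1L, floor(length(I_row) / segment))
  segsd <- vapply(seq_len(ns), function(k)
    sd(I_row[((k - 1) * segment + 1):(k * segment)]), 0)
  s0 <- quantile(segsd, 0.25, names = FALSE)
  if (is.na(s0) || s0 == 0) s0 <- sd(I_row)
  core <- I_row[abs(I_row) <= 4 * s0]
  if (length(core) < 30) core <- I_row
  iqr <- diff(quantile(core, c(0.25, 0.75), names = FALSE))
  bw <- if (iqr > 0) 2 * iqr / length(core)^(1 / 3) else s0 / 2
  nb <- max(9L, ceiling(diff(range(core)) / bw))
  breaks <- seq(min(core), max(core), length.out = nb + 1L)
  h <- graphics::hist(core, breaks = breaks, plot = FALSE)
  pk <- max(h$counts)
  # parametrized relative to (pk, s0) so the optimization path is invariant
  # to a positive rescaling of the input
  obj <- function(p) {
    A <- p[1] * pk; sig <- p[2] * s0; C <- p[3] * pk
    sum((h$counts - A * exp(-h$mids^2 / (2 * sig^2)) - C)^2)
  }
  fit <- optim(c(1, 1, 0), obj, method = "L-BFGS-B",
               lower = c(1e-6, 0.2, 0), upper = c(10, 4, 1))
  structure(fit$par[2] * s0, degenerate = FALSE)
}

#' Threshold-crossing candidate event windows
#'
#' Maximal runs of consecutive processed-signal samples strictly exceeding
#' `multiplier * sigma`. Because consecutive processed samples share most of
#' their integration window, a single transient can flicker across the
#' threshold; suprathreshold runs separated by fewer than `merge_gap`
#' subthreshold samples are therefore merged before the minimum-length rule
#' is applied. Merged runs spanning fewer than `min_run` suprathreshold
#' samples are discarded. Runs touching the signal edges count if they
#' contain `min_run` samples.
#'
#' @param I_row one neuron's processed signal.
#' @param sigma its noise SD (> 0), e.g. from [estimate_noise_sigma()].
#' @param multiplier threshold in units of sigma (default 3).
#' @param min_run minimum run length (default 5 samples).
#' @param merge_gap maximum subthreshold gap (samples) closed before the
#'   length rule (default 10, about 0.17 s at 59 Hz).
#' @return data frame with columns `start`, `end` (1-based indices into
#'   `I_row`, inclusive).
#' @export
detect_events <- function(I_row, sigma, multiplier = 3, min_run = 5,
                          merge_gap = 10) {
  if (sigma <= 0) stopf("`sigma` must be positive")
  above <- I_row > multiplier * sigma
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) > 1L) {
    merged <- list(runs[1, ])
    for (k in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs[k, 1] - last[2] - 1L < merge_gap) {
        merged[[length(merged)]][2] <- runs[k, 2]
      } else merged[[length(merged) + 1L]] <- runs[k, ]
    }
    runs <- do.call(rbind, merged)
  }
  if (!nrow(runs)) return(data.frame(start = integer(0), end = integer(0)))
  keep <- vapply(seq_len(nrow(runs)), function(k)
    sum(above[runs[k, 1]:runs[k, 2]]) >= min_run, TRUE)
  data.frame(start = runs[keep, 1], end = runs[keep, 2])
}

#' Sigmoidal onset/offset estimation for one calcium event
#'
#' Least-squares fit of the four-parameter sigmoid
#' `F(t) = base + A / (1 + exp(-(t - t0) / tau))` to the rising phase of the
#' raw fluorescence trace around a candidate window, padded by 0.5 s where
#' available. The onset and offset are the times at which the fitted curve
#' crosses 5% and 95% of the plateau: `t0 -/+ tau * log(19)`.
#'
#' @param F_row one neuron's raw fluorescence trace.
#' @param window a single candidate window (row of [detect_events()] output,
#'   indices in processed-signal coordinates).
#' @param frame_rate acquisition rate (Hz).
#' @param integration_window frames spanned by the sliding integration
#'   (defaults to `round(frame_rate)`), used to map processed-signal indices
#'   back onto raw frames.
#' @return list with `onset`, `offset` (s from recording start), `t0`, `tau`,
#'   `base`, `amplitude`; or `NULL` when the fit does not converge.
#' @export
fit_onset_offset <- function(F_row, window, frame_rate,
                             integration_window = round(frame_rate)) {
  pad <- round(0.5 * frame_rate)
  # I[j'] compares frames j' and j' + integration_window: the rise happens
  # inside that span, ending at the fluorescence peak
  lo <- max(1L, window$start - pad)
  peak_span <- window$start:min(length(F_row), window$end + integration_window)
  span_min <- min(F_row[peak_span]); span_max <- max(F_row[peak_span])
  # end the rising phase at the first sample reaching 90% of the excursion;
  # the global maximum can sit deep in the noisy decay
  peak_at <- peak_span[which(F_row[peak_span] >=
                               span_min + 0.9 * (span_max - span_min))[1]]
  idx <- lo:peak_at
  if (length(idx) < 5L) return(NULL)
  tt <- (idx - 1) / frame_rate
  yy_raw <- F_row[idx]
  # fit on a unit-normalized copy so the optimization path (and therefore
  # the estimated times) is independent of trace offset and gain
  y_lo <- min(yy_raw); y_rng <- max(yy_raw) - y_lo
  if (y_rng <= 0) return(NULL)
  yy <- (yy_raw - y_lo) / y_rng
  # smoothed level crossings give noise-tolerant t0 starting points
  ys <- stats::runmed(yy, 3)
  rng <- range(ys)
  t0_starts <- unique(vapply(c(0.25, 0.5, 0.75), function(f) {
    cross <- which(ys >= rng[1] + f * diff(rng))[1]
    tt[if (is.na(cross)) length(tt) else cross]
  }, 0))
  resid_fn <- function(p)
    yy - (p[1] + p[2] / (1 + exp(-(tt - p[3]) / p[4])))
  best <- NULL
  for (t0i in t0_starts) for (taui in c(0.05, 0.15)) {
    par0 <- c(base = 0, A = diff(rng), t0 = t0i, tau = taui)
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fn,
                         lower = c(-Inf, 1e-12, min(tt), 1e-4),
                         upper = c(Inf, Inf, max(tt), 0.5),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$par))) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(NULL)
  p <- as.list(best$par)
  names(p) <- c("base", "A", "t0", "tau")
  p$base <- y_lo + y_rng * p$base
  p$A <- y_rng * p$A
  list(onset = p$t0 - p$tau * log(19), offset = p$t0 + p$tau * log(19),
       t0 = p$t0, tau = p$tau, base = p$base, amplitude = p$A)
}

#' Detect calcium events in a full recording
#'
#' Runs the complete detection chain per neuron: sliding-window differencing
#' ([process_traces()]), noise-SD estimation ([estimate_noise_sigma()]),
#' thresholding at `multiplier * sigma` for at least `min_run` consecutive
#' samples ([detect_events()]), and sigmoidal onset/offset estimation
#' ([fit_onset_offset()]). Events whose sigmoid fit fails to converge are
#' dropped (counted in the QC attribute).
#'
#' @param rec a [fluorescence_recording()].
#' @param multiplier threshold multiplier (default 3).
#' @param min_run minimum suprathreshold run (default 5).
#' @return data frame of class `"calcium_events"` with columns `neuron`,
#'   `onset`, `offset` (s); attribute `qc` lists per-neuron sigma, candidate
#'   and dropped-event counts.
#' @examples
#' syn <- spikes_to_fluorescence(list(c(2, 6)), duration = 10,
#'                               params = calcium_kernel_params(noise_sd = 0.02),
#'                               seed = 1)
#' detect_calcium_events(syn$recording)
#' @export
detect_calcium_events <- function(rec, multiplier = 3, min_run = 5) {
  ps <- process_traces(rec)
  fr <- ps$frame_rate
  rows <- list()
  qc <- data.frame(neuron = seq_len(nrow(rec)), sigma = NA_real_,
                   candidates = 0L, dropped = 0L, degenerate = FALSE)
  for (i in seq_len(nrow(rec))) {
    sig <- estimate_noise_sigma(ps$I[i, ], segment = ps$window)
    qc$sigma[i] <- as.numeric(sig)
    if (isTRUE(attr(sig, "degenerate")) || sig <= 0) {
      qc$degenerate[i] <- TRUE
      next
    }
    wins <- detect_events(ps$I[i, ], sig, multiplier, min_run)
    qc$candidates[i] <- nrow(wins)
    if (!nrow(wins)) next
    for (k in seq_len(nrow(wins))) {
      f <- fit_onset_offset(rec[i, ], wins[k, ], fr, ps$window)
      if (is.null(f)) {
        qc$dropped[i] <- qc$dropped[i] + 1L
        warning(sprintf("neuron %d: sigmoid fit failed for window %d", i, k),
                call. = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(neuron = i, onset = f$onset,
                                              offset = f$offset)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(neuron = integer(0), onset = numeric(0), offset = numeric(0))
  attr(out, "qc") <- qc
  attr(out, "frame_rate") <- fr
  attr(out, "duration") <- ncol(rec) / fr
  class(out) <- c("calcium_events", "data.frame")
  out
}
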
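#' Parameters of the synthetic calcium transient kernel
#'
#' Each event contributes a double-exponential transient
#' `K(t) = exp(-t / decay_tau) - exp(-t / rise_tau)` (t >= 0), scaled so its
#' peak equals `amplitude`. Defaults emulate somatic OGB-1-like transients
#' sampled at 59 Hz: 50-ms rise, 1-s decay.
#'
#' @param rise_tau rise time constant (s), < `decay_tau`.
#' @param decay_tau decay time constant (s).
#' @param amplitude peak amplitude (fluorescence units).
#' @param baseline constant baseline level.
#' @param noise_sd white Gaussian frame-noise SD.
#' @param frame_rate sampling rate (Hz).
#' @param drift_per_s optional linear baseline drift (units/s, default 0) for
#'   stressing shift-robustness of detectors.
#' @return list of class `"calcium_kernel_params"`.
#' @export
calcium_kernel_params <- function(rise_tau = 0.05, decay_tau = 1,
                                  amplitude = 1, baseline = 10,
                                  noise_sd = 0.05, frame_rate = 59,
                                  drift_per_s = 0) {
  if (rise_tau >= decay_tau) stopf("`rise_tau` must be below `decay_tau`")
  if (amplitude <= 0) stopf("`amplitude` must be positive")
  if (noise_sd < 0) stopf("`noise_sd` must be nonnegative")
  if (frame_rate <= 0) stopf("`frame_rate` must be positive")
  structure(list(rise_tau = rise_tau, decay_tau = decay_tau,
                 amplitude = amplitude, baseline = baseline,
                 noise_sd = noise_sd, frame_rate = frame_rate,
                 drift_per_s = drift_per_s),
            class = "calcium_kernel_params")
}

#' Analytic peak time of the double-exponential kernel
#'
#' The kernel `exp(-t/decay) - exp(-t/rise)` peaks at
#' `t* = log(decay/rise) * decay * rise / (decay - rise)` after the event.
#'
#' @param params a [calcium_kernel_params()].
#' @return peak time (s).
#' @export
kernel_peak_time <- function(params) {
  with(params, log(decay_tau / rise_tau) * decay_tau * rise_tau /
         (decay_tau - rise_tau))
}

#' Render event onsets into a noisy fluorescence recording
#'
#' Linear superposition of the double-exponential kernel at every event
#' time, plus a constant baseline, optional linear drift, and i.i.d.
#' Gaussian frame noise. Ground truth (the generating onsets and flags) is
#' returned alongside the recording.
#'
#' @param onsets list of per-neuron event-time vectors (s), a
#'   [spike_raster()] (times converted from ms), or an [onset_series()].
#' @param params a [calcium_kernel_params()].
#' @param duration recording length (s); inferred from the latest event
#'   + 3 decay constants when missing.
#' @param seed integer seed for the frame noise.
#' @param gaba optional per-neuron logical flags, stored as ground truth.
#' @return list with `recording` (a [fluorescence_recording()]) and `truth`
#'   (list: `onsets`, `gaba`, `params`).
#' @examples
#' syn <- spikes_to_fluorescence(list(c(1, 4), 2.5), duration = 8, seed = 1)
#' syn$recording
#' @export
spikes_to_fluorescence <- function(onsets, params = calcium_kernel_params(),
                                   duration = NULL, seed = NULL,
                                   gaba = NULL) {
  if (inherits(onsets, "spike_raster")) {
    n <- attr(onsets, "n_neurons")
    if (is.null(duration)) duration <- attr(onsets, "duration") / 1000
    onsets <- lapply(seq_len(n), function(i)
      onsets$time[onsets$neuron == i] / 1000)
  } else if (inherits(onsets, "onset_series")) {
    if (is.null(duration)) duration <- onsets$duration
    onsets <- onsets$onsets
  }
  if (is.null(duration))
    duration <- max(c(0, unlist(onsets))) + 3 * params$decay_tau
  fr <- params$frame_rate
  n_frames <- ceiling(duration * fr)
  tt <- (seq_len(n_frames) - 1) / fr
  # normalize kernel peak to `amplitude`
  peak <- with(params, exp(-kernel_peak_time(params) / decay_tau) -
                 exp(-kernel_peak_time(params) / rise_tau))
  Fm <- with_seed(seed, {
    t(vapply(onsets, function(ev) {
      y <- rep(params$baseline, n_frames) + params$drift_per_s * tt
      for (t0 in ev) {
        d <- tt - t0
        pos <- d >= 0
        y[pos] <- y[pos] + params$amplitude / peak *
          (exp(-d[pos] / params$decay_tau) - exp(-d[pos] / params$rise_tau))
      }
      if (params$noise_sd > 0) y <- y + rnorm(n_frames, 0, params$noise_sd)
      y
    }, numeric(n_frames)))
  })
  list(recording = fluorescence_recording(Fm, frame_rate = fr, gaba = gaba),
       truth = list(onsets = onsets, gaba = gaba, params = params))
}

#' Ground-truthed feed-forward chain of activation sweeps
#'
#' Generates repeated activation sweeps through an `n_stages`-long chain:
#' sweep `s` activates stage 1 at time `s * sweep_interval`, and each later
#' stage `delay_ms` after the previous one, plus Gaussian jitter. The known
#' edge set is the chain `1 -> 2 -> ... -> n_stages`.
#'
#' @param n_stages chain length (>= 2).
#' @param delay_ms inter-stage propagation delay (ms, default 120).
#' @param jitter_ms SD of the Gaussian timing jitter (ms, default 10).
#' @param n_repetitions number of sweeps (default 50).
#' @param sweep_interval time between sweep starts (s, default 10).
#' @param seed integer seed.
#' @return list with `onsets` (an [onset_series()]) and `truth` (data frame
#'   of true directed edges `from`, `to`).
#' @export
make_chain_population <- function(n_stages = 5, delay_ms = 120,
                                  jitter_ms = 10, n_repetitions = 50,
                                  sweep_interval = 10, seed = NULL) {
  if (n_stages < 2) stopf("`n_stages` must be >= 2")
  with_seed(seed, {
    starts <- (seq_len(n_repetitions) - 1) * sweep_interval + 1
    on <- lapply(seq_len(n_stages), function(stage) {
      jit <- if (stage == 1) 0 else rnorm(n_repetitions, 0, jitter_ms / 1000)
      sort(starts + (stage - 1) * delay_ms / 1000 + jit)
    })
    duration <- max(unlist(on)) + 1
    list(onsets = onset_series(on, duration),
         truth = data.frame(from = seq_len(n_stages - 1),
                            to = 2:n_stages))
  })
}

#' Independent-Poisson onset population (null fixture)
#'
#' Homogeneous Poisson event trains, independent across neurons; the
#' matched null for false-positive calibration of the connectivity
#' inference.
#'
#' @param n_neurons population size.
#' @param rate_hz event rate per neuron (Hz).
#' @param duration recording length (s).
#' @param min_gap optional dead time (s): events closer than this to their
#'   predecessor are thinned out. Default 0 (pure Poisson). Calcium-imaging
#'   fixtures should keep events farther apart than the 1-s detector
#'   integration window, below which transients are unresolvable by design.
#' @param seed integer seed.
#' @return an [onset_series()].
#' @export
make_poisson_population <- function(n_neurons, rate_hz, duration,
                                    min_gap = 0, seed = NULL) {
  with_seed(seed, {
    on <- lapply(seq_len(n_neurons), function(i) {
      k <- stats::rpois(1, rate_hz * duration)
      x <- sort(runif(k, 0, duration))
      if (min_gap > 0 && length(x) > 1) {
        keep <- rep(TRUE, length(x))
        last <- x[1]
        for (q in 2:length(x)) {
          if (x[q] - last < min_gap) keep[q] <- FALSE else last <- x[q]
        }
        x <- x[keep]
      }
      x
    })
    onset_series(on, duration)
  })
}

#' Synthetic extracellular trace with embedded spike templates
#'
#' A biphasic 1-ms spike template (one negative then one positive half-sine
#' lobe) is added at known times to white Gaussian noise. `snr` is the peak
#' template amplitude over the noise SD.
#'
#' @param duration_s trace length (s).
#' @param fs sampling rate (Hz, default 25000).
#' @param spike_times spike times (s); default draws a 5-Hz Poisson train
#'   with a 5-ms dead time.
#' @param snr peak signal-to-noise ratio (default 8).
#' @param noise_sd noise SD (default 1; template amplitude is then `snr`).
#' @param seed integer seed.
#' @return list with `signal` (numeric vector), `fs`, `spike_times`.
#' @export
synthetic_ephys_trace <- function(duration_s, fs = 25000, spike_times = NULL,
                                  snr = 8, noise_sd = 1, seed = NULL) {
  with_seed(seed, {
    n <- round(duration_s * fs)
    x <- rnorm(n, 0, noise_sd)
    if (is.null(spike_times)) {
      k <- stats::rpois(1, 5 * duration_s)
      spike_times <- sort(runif(k, 0.01, duration_s - 0.01))
      spike_times <- spike_times[c(TRUE, diff(spike_times) > 0.005)]
    }
    half <- round(fs * 5e-4)                       # 0.5 ms per lobe
    lobe <- sin(pi * seq_len(half) / (half + 1))
    template <- snr * noise_sd * c(-lobe, 0.6 * lobe)
    for (t0 in spike_times) {
      i0 <- round(t0 * fs)
      idx <- i0 + seq_along(template) - 1L
      ok <- idx >= 1 & idx <= n
      x[idx[ok]] <- x[idx[ok]] + template[ok]
    }
    list(signal = x, fs = fs, spike_times = spike_times)
  })
}
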
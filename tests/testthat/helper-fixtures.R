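# shared fixtures and scoring helpers

# greedy one-to-one matching of detected event times against ground truth
match_events <- function(true, det, tol) {
  tp <- 0
  errs <- numeric(0)
  used <- rep(FALSE, length(det))
  for (t0 in true) {
    if (!length(det)) next
    d <- abs(det - t0)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) {
      tp <- tp + 1
      used[j] <- TRUE
      errs <- c(errs, det[j] - t0)
    }
  }
  list(tp = tp, errs = errs)
}

# precision / recall / median onset error of a calcium detection run
score_calcium <- function(true_onsets, events, n_neurons, tol = 1.0) {
  tp <- 0; fp <- 0; nt <- 0; errs <- numeric(0)
  for (i in seq_len(n_neurons)) {
    det <- events$onset[events$neuron == i]
    m <- match_events(true_onsets[[i]], det, tol)
    tp <- tp + m$tp
    fp <- fp + length(det) - m$tp
    nt <- nt + length(true_onsets[[i]])
    errs <- c(errs, m$errs)
  }
  list(recall = tp / nt, precision = tp / (tp + fp),
       median_err = median(abs(errs)))
}

# well-separated synthetic calcium recording with known onsets;
# noise_sd set for a given detection-domain peak SNR (amplitude 1)
calcium_fixture <- function(n_neurons = 15, duration = 120, snr = 5,
                            seed = 42, noise_seed = 7) {
  pop <- make_poisson_population(n_neurons, 0.09, duration, min_gap = 2,
                                 seed = seed)
  onsets <- lapply(pop$onsets, function(x) x[x > 2 & x < duration - 5])
  syn <- spikes_to_fluorescence(
    onsets, duration = duration,
    params = calcium_kernel_params(noise_sd = 1 / (snr * sqrt(2)),
                                   amplitude = 1),
    seed = noise_seed)
  list(onsets = onsets, recording = syn$recording)
}

# naive double-loop evaluation of the normalized lagged cross-correlation,
# kept deliberately independent of the package implementation
naive_cross_correlation <- function(a, b, max_lag) {
  N <- length(a)
  am <- mean(a); bm <- mean(b)
  sa <- sqrt(sum((a - am)^2) / N)
  sb <- sqrt(sum((b - bm)^2) / N)
  vapply(-max_lag:max_lag, function(tau) {
    acc <- 0
    for (t in seq_len(N)) {
      tb <- t + tau
      if (tb >= 1 && tb <= N) acc <- acc + (a[t] - am) * (b[tb] - bm)
    }
    acc / (N * sa * sb)
  }, 0)
}
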
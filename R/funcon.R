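#' Onset-series container
#'
#' Per-neuron ordered event-onset times, the common recording duration, and
#' the sampling period of the underlying recording.
#'
#' @param onsets list of numeric vectors (onset times in s, one per neuron).
#' @param duration recording duration (s).
#' @param dt sampling period (s), default `1/59`.
#' @return list of class `"onset_series"`.
#' @export
onset_series <- function(onsets, duration, dt = 1 / 59) {
  onsets <- lapply(onsets, function(x) sort(as.numeric(x)))
  bad <- vapply(onsets, function(x)
    length(x) && (min(x) < 0 || max(x) > duration), TRUE)
  if (any(bad)) stopf("onset times must lie in [0, duration]")
  structure(list(onsets = onsets, duration = duration, dt = dt),
            class = "onset_series")
}

#' Convert a calcium-event table or spike raster to an onset series
#'
#' For rasters, spike times (ms) are converted to seconds.
#'
#' @param x a `"calcium_events"` table or a [spike_raster()].
#' @param n_neurons override for the neuron count.
#' @param dt sampling period (s).
#' @return an [onset_series()].
#' @export
as_onset_series <- function(x, n_neurons = NULL, dt = 1 / 59) {
  if (inherits(x, "calcium_events")) {
    n <- if (is.null(n_neurons)) nrow(attr(x, "qc")) else n_neurons
    dur <- attr(x, "duration")
    on <- lapply(seq_len(n), function(i) x$onset[x$neuron == i])
    onset_series(on, dur, dt)
  } else if (inherits(x, "spike_raster")) {
    n <- if (is.null(n_neurons)) attr(x, "n_neurons") else n_neurons
    on <- lapply(seq_len(n), function(i) x$time[x$neuron == i] / 1000)
    onset_series(on, attr(x, "duration") / 1000, dt)
  } else stopf("cannot convert object of class %s", class(x)[1])
}

#' Signed lags between two onset trains
#'
#' For every onset of neuron `j`, the nearest onset of neuron `k` within
#' `+/- max_lag` contributes one signed lag `t_k - t_j`; onsets of `j` with
#' no `k` event inside the window contribute nothing.
#'
#' @param onsets_j,onsets_k sorted onset times (s).
#' @param max_lag window half-width (s), default 0.5.
#' @return numeric vector of lags (possibly empty).
#' @export
pairwise_lags <- function(onsets_j, onsets_k, max_lag = 0.5) {
  if (!length(onsets_j) || !length(onsets_k)) return(numeric(0))
  onsets_k <- sort(onsets_k)
  pos <- findInterval(onsets_j, onsets_k)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(onsets_k))
  d_lo <- onsets_k[lo] - onsets_j
  d_hi <- onsets_k[hi] - onsets_j
  lag <- ifelse(abs(d_lo) <= abs(d_hi), d_lo, d_hi)
  lag[abs(lag) <= max_lag]
}

#' Directional decision for one neuron pair
#'
#' A functional edge is declared only when the lag distribution rejects both
#' null shapes that characterize non-causal timing: a one-sample t-test must
#' reject zero mean (excluding synchronous co-activation) and a
#' Kolmogorov-Smirnov test must reject uniformity on `[-max_lag, max_lag]`
#' (excluding unrelated activity), both at level `alpha`. The edge direction
#' follows the sign of the mean lag (positive mean, i.e. `k` after `j`,
#' gives `j -> k`).
#'
#' @param lags signed lags from [pairwise_lags()].
#' @param alpha test level (default 0.05).
#' @param max_lag lag window half-width used to form `lags` (s).
#' @param min_lags minimum number of lags required before testing; below it
#'   the decision is `"none"` with `insufficient = TRUE`.
#' @return list with `decision` (`"none"`, `"jk"` or `"kj"`), `p_t`, `p_ks`,
#'   `mean_lag`, `n`, `insufficient`.
#' @export
test_direction <- function(lags, alpha = 0.05, max_lag = 0.5, min_lags = 5) {
  if (length(lags) < min_lags)
    return(list(decision = "none", p_t = NA_real_, p_ks = NA_real_,
                mean_lag = if (length(lags)) mean(lags) else NA_real_,
                n = length(lags), insufficient = TRUE))
  # (near-)constant lag sets make the t statistic degenerate: the mean is
  # then known exactly, so reject unless it is zero
  p_t <- tryCatch(t.test(lags, mu = 0)$p.value,
                  error = function(e) if (mean(lags) == 0) 1 else 0)
  if (sd(lags) == 0) p_t <- if (mean(lags) == 0) 1 else 0
  p_ks <- suppressWarnings(
    ks.test(lags, "punif", -max_lag, max_lag)$p.value)
  dec <- "none"
  if (p_t < alpha && p_ks < alpha)
    dec <- if (mean(lags) > 0) "jk" else "kj"
  list(decision = dec, p_t = p_t, p_ks = p_ks, mean_lag = mean(lags),
       n = length(lags), insufficient = FALSE)
}

#' Infer a directed functional-connectivity graph from onset series
#'
#' Every unordered neuron pair `(j, k)`, `j < k`, is evaluated once: the lag
#' set of `k`'s onsets around `j`'s onsets ([pairwise_lags()]) is passed to
#' the dual statistical gate ([test_direction()]), producing at most one
#' directed edge per pair. No multiple-testing correction is applied by
#' default (`p_adjust = "none"`); set `p_adjust = "BH"` for a
#' Benjamini-Hochberg variant.
#'
#' @param onsets an [onset_series()].
#' @param alpha test level.
#' @param max_lag lag window half-width (s).
#' @param min_lags minimum lags per pair.
#' @param p_adjust `"none"` (default) or a method name for [stats::p.adjust()]
#'   applied to both test families across pairs.
#' @return object of class `"functional_graph"`: list with `edges` (data
#'   frame `from`, `to`, `mean_lag`, `n`, `p_t`, `p_ks`), `n_neurons`,
#'   `in_degree`, `out_degree`.
#' @export
build_functional_graph <- function(onsets, alpha = 0.05, max_lag = 0.5,
                                   min_lags = 5, p_adjust = "none") {
  n <- length(onsets$onsets)
  if (n < 2) stopf("need at least 2 neurons")
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  res <- lapply(seq_len(nrow(pairs)), function(q) {
    j <- pairs[q, 1]; k <- pairs[q, 2]
    lg <- pairwise_lags(onsets$onsets[[j]], onsets$onsets[[k]], max_lag)
    c(list(j = j, k = k),
      test_direction(lg, alpha = alpha, max_lag = max_lag,
                     min_lags = min_lags))
  })
  p_t <- vapply(res, function(r) r$p_t, 0)
  p_ks <- vapply(res, function(r) r$p_ks, 0)
  if (!identical(p_adjust, "none")) {
    p_t <- stats::p.adjust(p_t, method = p_adjust)
    p_ks <- stats::p.adjust(p_ks, method = p_adjust)
  }
  rows <- list()
  for (q in seq_along(res)) {
    r <- res[[q]]
    if (r$insufficient || is.na(p_t[q])) next
    if (p_t[q] < alpha && p_ks[q] < alpha) {
      from <- if (r$mean_lag > 0) r$j else r$k
      to <- if (r$mean_lag > 0) r$k else r$j
      rows[[length(rows) + 1L]] <- data.frame(
        from = from, to = to, mean_lag = abs(r$mean_lag), n = r$n,
        p_t = p_t[q], p_ks = p_ks[q])
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from = integer(0), to = integer(0), mean_lag = numeric(0),
               n = integer(0), p_t = numeric(0), p_ks = numeric(0))
  structure(list(edges = edges, n_neurons = n,
                 in_degree = tabulate(edges$to, n),
                 out_degree = tabulate(edges$from, n)),
            class = "functional_graph")
}

#' @export
print.functional_graph <- function(x, ...) {
  cat(sprintf("<functional_graph> %d neurons, %d directed edges\n",
              x$n_neurons, nrow(x$edges)))
  invisible(x)
}

#' Top-ranked INPUT or OUTPUT nodes of a functional graph
#'
#' Ranks neurons by in-degree (`mode = "input"`) or out-degree
#' (`mode = "output"`); ties are broken by ascending node id. Nodes with zero
#' degree are excluded.
#'
#' @param graph a [build_functional_graph()] result.
#' @param mode `"input"` or `"output"`.
#' @param top_n list length (default 10).
#' @return integer vector of node ids, highest degree first.
#' @export
rank_nodes <- function(graph, mode = c("input", "output"), top_n = 10) {
  mode <- match.arg(mode)
  deg <- if (mode == "input") graph$in_degree else graph$out_degree
  ids <- which(deg > 0)
  ids <- ids[order(-deg[ids], ids)]
  head(ids, top_n)
}

#' Normalized lagged cross-correlation of two binned series
#'
#' `CC_ab(tau) = sum_t (a_t - <a>) (b_{t+tau} - <b>) / (T sigma_a sigma_b)`
#' over the overlapping samples, where `<a>`, `sigma_a` are the full-series
#' mean and population SD and `T` is the full series length. Normalizing by
#' `T` makes the autocorrelation equal 1 at zero lag and bounds `|CC|` by 1.
#' Positive `tau_max` means series `a` leads (`b` repeats `a` after a delay).
#'
#' @param a,b equal-length numeric vectors (e.g. binned onset indicators).
#' @param max_lag_samples maximal lag in samples; defaults to
#'   `round(max_lag_s / dt)` when `dt` is given.
#' @param dt sampling period (s), used with `max_lag_s`.
#' @param max_lag_s maximal lag in seconds (default 1).
#' @return list of class `"cross_correlation"`: `tau` (samples), `cc`,
#'   `cc_max`, `tau_max` (samples), `tau_max_s` (if `dt` given).
#' @examples
#' a <- as.numeric(runif(200) < 0.1)
#' cc <- cross_correlation(a, a, max_lag_samples = 20)
#' c(cc$cc_max, cc$tau_max)  # 1, 0
#' @export
cross_correlation <- function(a, b, max_lag_samples = NULL, dt = NULL,
                              max_lag_s = 1) {
  if (length(a) != length(b)) stopf("series must have equal length")
  N <- length(a)
  if (is.null(max_lag_samples)) {
    if (is.null(dt)) stopf("give either `max_lag_samples` or `dt`")
    max_lag_samples <- round(max_lag_s / dt)
  }
  sa <- sqrt(mean((a - mean(a))^2))
  sb <- sqrt(mean((b - mean(b))^2))
  if (sa == 0 || sb == 0)
    stopf("undefined correlation: a series has zero variance")
  am <- a - mean(a); bm <- b - mean(b)
  taus <- -max_lag_samples:max_lag_samples
  cc <- vapply(taus, function(tau) {
    if (tau >= 0) {
      t_idx <- seq_len(N - tau)
      sum(am[t_idx] * bm[t_idx + tau])
    } else {
      t_idx <- seq_len(N + tau) - tau
      sum(am[t_idx] * bm[t_idx + tau])
    }
  }, 0) / (N * (sa * sb))   # grouped so CC_ab(tau) = CC_ba(-tau) bit-exactly
  best <- which(cc == max(cc))
  best <- best[which.min(abs(taus[best]))]
  out <- list(tau = taus, cc = cc, cc_max = cc[best], tau_max = taus[best])
  if (!is.null(dt)) out$tau_max_s <- taus[best] * dt
  class(out) <- "cross_correlation"
  out
}

#' @export
print.cross_correlation <- function(x, ...) {
  cat(sprintf("<cross_correlation> CC_max = %.3f at tau = %d samples\n",
              x$cc_max, x$tau_max))
  invisible(x)
}

#' Bin onset times into a binary indicator series
#'
#' @param onsets onset times (s).
#' @param duration recording duration (s).
#' @param dt bin width (s).
#' @return 0/1 vector of length `ceiling(duration / dt)`.
#' @export
bin_onsets <- function(onsets, duration, dt = 1 / 59) {
  n_bins <- ceiling(duration / dt)
  v <- numeric(n_bins)
  idx <- pmin(pmax(floor(onsets / dt) + 1L, 1L), n_bins)
  v[idx] <- 1
  v
}

#' Per-neuron average correlation and activation lag
#'
#' For every neuron pair the lagged cross-correlation maximum `CC_max` and
#' its lag `tau_max` are computed on the binned onset indicators; neuron
#' `i`'s summary averages `CC_max` and `tau_max` over the partners with
#' positive `CC_max`. Positive `<tau_max>` means the neuron tends to lead
#' its partners.
#'
#' @param onsets an [onset_series()].
#' @param max_lag_s maximal lag (s), default 1.
#' @param gaba optional per-neuron logical flags carried into the output.
#' @return data frame of class `"correlation_summary"` with columns
#'   `neuron`, `cc_max_mean`, `tau_max_mean` (s), `n_partners`, `gaba`;
#'   neurons with no positive-correlation partner get `NA` summaries and
#'   `n_partners = 0`.
#' @export
summarize_correlations <- function(onsets, max_lag_s = 1, gaba = NULL) {
  n <- length(onsets$onsets)
  if (n < 2) stopf("need at least 2 neurons")
  dt <- onsets$dt
  series <- lapply(onsets$onsets, bin_onsets, duration = onsets$duration,
                   dt = dt)
  L <- round(max_lag_s / dt)
  ccm <- matrix(NA_real_, n, n); tm <- matrix(NA_real_, n, n)
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    res <- tryCatch(cross_correlation(series[[j]], series[[k]],
                                      max_lag_samples = L),
                    error = function(e) NULL)
    if (is.null(res)) next
    ccm[j, k] <- res$cc_max; tm[j, k] <- res$tau_max * dt
    ccm[k, j] <- res$cc_max; tm[k, j] <- -res$tau_max * dt
  }
  out <- data.frame(neuron = seq_len(n), cc_max_mean = NA_real_,
                    tau_max_mean = NA_real_, n_partners = 0L)
  for (i in seq_len(n)) {
    ok <- which(!is.na(ccm[i, ]) & ccm[i, ] > 0)
    ok <- setdiff(ok, i)
    if (length(ok)) {
      out$cc_max_mean[i] <- mean(ccm[i, ok])
      out$tau_max_mean[i] <- mean(tm[i, ok])
      out$n_partners[i] <- length(ok)
    }
  }
  out$gaba <- if (is.null(gaba)) NA else gaba
  class(out) <- c("correlation_summary", "data.frame")
  out
}

#' Time lag vs correlation scatter
#'
#' The standard diagnostic scatter of per-neuron `<tau_max>` against
#' `<CC_max>`, marking GABAergic neurons when flagged.
#'
#' @param x a [summarize_correlations()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.correlation_summary <- function(x, ...) {
  col <- ifelse(!is.na(x$gaba) & x$gaba, "red", "black")
  graphics::plot(x$tau_max_mean, x$cc_max_mean, col = col, pch = 19,
                 xlab = expression(paste("<", tau[max], "> (s)")),
                 ylab = expression(paste("<", CC[max], ">")), ...)
  invisible(x)
}
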
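#' Population instantaneous firing-rate profile
#'
#' Bins all spikes of a raster into fixed-width time bins and records, per
#' bin, the total spike count and the fraction of neurons active (>= 1
#' spike). Spike counts are conserved exactly.
#'
#' @param raster a [spike_raster()].
#' @param bin_size bin width in ms (default 100).
#' @return data frame of class `"ifr_profile"` with columns `time` (bin left
#'   edge, ms), `count`, `fraction_active`; attributes `bin_size`,
#'   `n_neurons`, `duration`.
#' @export
population_ifr <- function(raster, bin_size = 100) {
  if (bin_size <= 0) stopf("`bin_size` must be positive")
  dur <- attr(raster, "duration")
  n <- attr(raster, "n_neurons")
  n_bins <- max(1L, ceiling(dur / bin_size))
  bin <- pmin(pmax(floor(raster$time / bin_size) + 1L, 1L), n_bins)
  counts <- tabulate(bin, n_bins)
  frac <- numeric(n_bins)
  if (nrow(raster)) {
    key <- unique((bin - 1L) * as.numeric(n) + raster$neuron)
    active_bin <- floor((key - 1) / n) + 1L
    tab <- tabulate(active_bin, n_bins)
    frac <- tab / n
  }
  out <- data.frame(time = (seq_len(n_bins) - 1L) * bin_size,
                    count = counts, fraction_active = frac)
  attr(out, "bin_size") <- bin_size
  attr(out, "n_neurons") <- n
  attr(out, "duration") <- dur
  class(out) <- c("ifr_profile", "data.frame")
  out
}

#' Detect network-wide synchronization events
#'
#' A network event is a maximal run of IFR bins whose active fraction is at
#' least `threshold_fraction`; runs separated by gaps shorter than
#' `min_separation` are merged into one event. The criterion and its defaults
#' are package choices (burst detectors in this field are conventionally
#' threshold-based); both knobs are exposed.
#'
#' @param ifr a [population_ifr()] profile.
#' @param threshold_fraction fraction of the population that must be active
#'   in a bin (0 < f <= 1, default 0.2).
#' @param min_separation events closer than this (ms) are merged (default
#'   200).
#' @return data frame of class `"network_events"` with columns `start`,
#'   `end` (ms), `participating_fraction` (max active fraction over the
#'   event's bins), `peak_rate` (max bin count / bin size, spikes per ms).
#' @export
detect_network_events <- function(ifr, threshold_fraction = 0.2,
                                  min_separation = 200) {
  check_scalar(threshold_fraction, "threshold_fraction", 1e-12, 1)
  bs <- attr(ifr, "bin_size")
  above <- ifr$fraction_active >= threshold_fraction
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (!is.null(dim(runs)) && nrow(runs) > 1L) {
    merged <- list(runs[1, ])
    for (k in 2:nrow(runs)) {
      gap_ms <- (runs[k, 1] - merged[[length(merged)]][2] - 1L) * bs
      if (gap_ms < min_separation) {
        merged[[length(merged)]][2] <- runs[k, 2]
      } else {
        merged[[length(merged) + 1L]] <- runs[k, ]
      }
    }
    runs <- do.call(rbind, merged)
  }
  if (is.null(dim(runs)) || nrow(runs) == 0L) {
    out <- data.frame(start = numeric(0), end = numeric(0),
                      participating_fraction = numeric(0),
                      peak_rate = numeric(0))
  } else {
    out <- data.frame(
      start = (runs[, 1] - 1L) * bs,
      end = runs[, 2] * bs,
      participating_fraction = vapply(seq_len(nrow(runs)), function(k)
        max(ifr$fraction_active[runs[k, 1]:runs[k, 2]]), 0),
      peak_rate = vapply(seq_len(nrow(runs)), function(k)
        max(ifr$count[runs[k, 1]:runs[k, 2]]) / bs, 0))
  }
  class(out) <- c("network_events", "data.frame")
  out
}

#' Network-event rate of a raster
#'
#' Convenience pipeline: IFR binning, event detection, and rate computation
#' with the initial transient excluded (events starting inside the transient
#' are dropped; the denominator is the analyzed span).
#'
#' @param raster a [spike_raster()].
#' @param bin_size IFR bin (ms).
#' @param threshold_fraction,min_separation passed to
#'   [detect_network_events()].
#' @param discard initial transient to exclude (ms, default 5000).
#' @return event rate in Hz.
#' @export
network_event_rate <- function(raster, bin_size = 100,
                               threshold_fraction = 0.2,
                               min_separation = 200, discard = 5000) {
  ev <- detect_network_events(population_ifr(raster, bin_size),
                              threshold_fraction, min_separation)
  ev <- ev[ev$start >= discard, , drop = FALSE]
  span_s <- (attr(raster, "duration") - discard) / 1000
  if (span_s <= 0) stopf("raster shorter than the discarded transient")
  nrow(ev) / span_s
}

#' Least-squares regression of event rate on population size
#'
#' Ordinary least squares of network-event rate (Hz) on total cell count.
#' When comparing simulations against cultures counted by nuclear staining,
#' the convention is `total_cells = 1.5 * n_neurons` (2:1 neuron/glia
#' ratio); apply that mapping to the x-values before calling (see
#' [total_cells()]).
#'
#' @param total_cells x-values (total cell counts).
#' @param rate y-values (event rate, Hz).
#' @return object of class `"rate_size_fit"`: `slope` (Hz/cell),
#'   `intercept` (Hz), `pearson_r`, `degenerate` (TRUE when the rates have
#'   zero variance, in which case `pearson_r` is reported as 0), and the
#'   input `points`.
#' @examples
#' f <- rate_size_regression(c(100, 200, 300), 0.00015 * c(100, 200, 300) + 0.01)
#' c(f$slope, f$pearson_r)
#' @export
rate_size_regression <- function(total_cells, rate) {
  if (length(total_cells) != length(rate))
    stopf("`total_cells` and `rate` must have equal length")
  if (length(rate) < 3) stopf("need at least 3 points")
  fit <- lm(rate ~ total_cells)
  degenerate <- var(rate) == 0 || var(total_cells) == 0
  r <- if (degenerate) 0 else cor(total_cells, rate)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 pearson_r = r, degenerate = degenerate,
                 points = data.frame(total_cells = total_cells, rate = rate)),
            class = "rate_size_fit")
}

#' @export
print.rate_size_fit <- function(x, ...) {
  cat(sprintf("<rate_size_fit> rate = %.3g * cells + %.3g (Pearson r = %.3f%s)\n",
              x$slope, x$intercept, x$pearson_r,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Map simulated neuron counts to total cell counts
#'
#' Applies the 2:1 neuron/glia convention used when placing simulated
#' networks on the same axis as stained-culture cell counts.
#'
#' @param n_neurons simulated neuron count(s).
#' @return `1.5 * n_neurons`.
#' @export
total_cells <- function(n_neurons) 1.5 * n_neurons
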
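#' Spike raster container
#'
#' A spike raster is the lingua franca between the simulator and the analysis
#' modules: an ordered table of `(neuron, time)` events plus the neuron count
#' and the recording duration.
#'
#' @param neuron integer neuron ids in `1..n_neurons`.
#' @param time spike times in ms, within `[0, duration]`.
#' @param n_neurons number of neurons the raster covers (silent neurons
#'   included).
#' @param duration recording duration in ms.
#' @return data frame of class `"spike_raster"` sorted by time, with
#'   attributes `n_neurons` and `duration`.
#' @export
spike_raster <- function(neuron, time, n_neurons, duration) {
  neuron <- as.integer(neuron)
  time <- as.numeric(time)
  if (length(neuron) != length(time))
    stopf("`neuron` and `time` must have equal length")
  if (length(neuron) && (min(neuron) < 1L || max(neuron) > n_neurons))
    stopf("neuron ids must lie in 1..n_neurons")
  if (length(time) && (min(time) < 0 || max(time) > duration))
    stopf("spike times must lie within [0, duration]")
  o <- order(time, neuron)
  out <- data.frame(neuron = neuron[o], time = time[o])
  attr(out, "n_neurons") <- as.integer(n_neurons)
  attr(out, "duration") <- as.numeric(duration)
  class(out) <- c("spike_raster", "data.frame")
  out
}

#' @export
print.spike_raster <- function(x, ...) {
  n <- attr(x, "n_neurons"); dur <- attr(x, "duration")
  cat(sprintf("<spike_raster> %d spikes, %d neurons, %.1f s\n",
              nrow(x), n, dur / 1000))
  if (nrow(x))
    cat(sprintf("  mean rate %.2f Hz/neuron\n", nrow(x) / n / (dur / 1000)))
  invisible(x)
}

#' @export
summary.spike_raster <- function(object, ...) {
  n <- attr(object, "n_neurons"); dur <- attr(object, "duration")
  per <- tabulate(object$neuron, n)
  structure(list(n_neurons = n, duration_ms = dur, n_spikes = nrow(object),
                 rate_hz = per / (dur / 1000)), class = "summary.spike_raster")
}

#' @export
print.summary.spike_raster <- function(x, ...) {
  cat(sprintf("%d neurons over %.1f s, %d spikes\n", x$n_neurons,
              x$duration_ms / 1000, x$n_spikes))
  cat("per-neuron rate (Hz):\n")
  print(summary(x$rate_hz))
  invisible(x)
}

#' Raster plot
#'
#' @param x a [spike_raster()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.spike_raster <- function(x, ...) {
  graphics::plot(x$time / 1000, x$neuron, pch = ".", xlab = "time (s)",
                 ylab = "neuron", ylim = c(1, attr(x, "n_neurons")), ...)
  invisible(x)
}

#' Read / write a spike raster as tab-separated text
#'
#' The on-disk format is a two-column TSV `neuron<TAB>time_ms` with a header
#' line, sorted by time. `n_neurons` and `duration` are stored in a `# key=value`
#' comment line so the file round-trips.
#'
#' @param raster a [spike_raster()].
#' @param path file path.
#' @return `read_raster()` returns a [spike_raster()]; `write_raster()`
#'   returns `path` invisibly.
#' @export
write_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_neurons=%d duration_ms=%.6f",
                     attr(raster, "n_neurons"), attr(raster, "duration")), con)
  writeLines("neuron\ttime_ms", con)
  if (nrow(raster))
    writeLines(sprintf("%d\t%.4f", raster$neuron, raster$time), con)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[0-9.eE+-]+", hdr))[[1]]
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                          vapply(kv, function(p) p[1], ""))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  spike_raster(df$neuron, df$time_ms, n_neurons = vals[["n_neurons"]],
               duration = vals[["duration_ms"]])
}
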
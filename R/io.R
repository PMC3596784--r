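#' Read a simulation configuration from JSON
#'
#' Keys: `n_neurons`, `frac_inhibitory`, `duration_ms`, `dt_ms`, `v_peak`,
#' `seed`, `noise {tau_ms, mean, sd}`, `topology {m, weight_mean, weight_sd}`.
#' Missing keys fall back to the package defaults.
#'
#' @param path JSON file.
#' @return list with `config` (a [sim_config()]) and `topology` (list `m`,
#'   `weight_mean`, `weight_sd`).
#' @export
read_sim_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  noise <- noise_params(
    tau_I = j$noise$tau_ms %||% 1,
    m_I = j$noise$mean %||% 25,
    s_I = j$noise$sd %||% 9)
  cfg <- sim_config(
    n_neurons = j$n_neurons,
    frac_inhibitory = j$frac_inhibitory %||% 0.25,
    duration = j$duration_ms %||% 600000,
    dt = j$dt_ms %||% 0.1,
    v_peak = j$v_peak %||% 40,
    seed = j$seed %||% 1,
    noise = noise)
  topo <- list(m = j$topology$m %||% 3,
               weight_mean = j$topology$weight_mean %||% 10,
               weight_sd = j$topology$weight_sd %||% 3.5)
  list(config = cfg, topology = topo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write fluorescence traces as CSV with a JSON sidecar
#'
#' The CSV holds one row per neuron, one column per frame, no header. The
#' sidecar (same path, extension `.json`) records `frame_rate_hz` and
#' optional per-neuron `gaba_flags`.
#'
#' @param rec a [fluorescence_recording()].
#' @param path CSV path.
#' @return `read_traces_csv()` returns a [fluorescence_recording()].
#' @export
write_traces_csv <- function(rec, path) {
  utils::write.table(unclass(rec), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(frame_rate_hz = attr(rec, "frame_rate"))
  if (!is.null(attr(rec, "gaba"))) meta$gaba_flags <- attr(rec, "gaba")
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  Fm <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(Fm) <- NULL
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  fr <- 59; gaba <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    fr <- meta$frame_rate_hz %||% 59
    gaba <- meta$gaba_flags
  }
  fluorescence_recording(Fm, frame_rate = fr, gaba = gaba)
}

#' Write a calcium-event table as TSV
#'
#' Columns `neuron`, `onset_s`, `offset_s`.
#'
#' @param events a `"calcium_events"` data frame.
#' @param path output path.
#' @export
write_events_tsv <- function(events, path) {
  df <- data.frame(neuron = events$neuron, onset_s = events$onset,
                   offset_s = events$offset)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}

#' Write a functional graph edge list as TSV
#'
#' @param graph a [build_functional_graph()] result.
#' @param path output TSV; a `.json` sidecar stores the degree summary.
#' @export
write_functional_graph <- function(graph, path) {
  write.table(graph$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(n_neurons = graph$n_neurons, in_degree = graph$in_degree,
         out_degree = graph$out_degree),
    paste0(tools::file_path_sans_ext(path), ".json"), auto_unbox = TRUE)
  invisible(path)
}
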
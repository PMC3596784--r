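#' Generate a directed scale-free connectivity graph
#'
#' Preferential-attachment generation after Batagelj and Brandes: nodes are
#' added one at a time and each new node contributes `m` edges whose far
#' endpoints are drawn uniformly from the running list of edge endpoints, so
#' attachment probability is proportional to current degree. The first node
#' contributes no edges (no seed clique), so the multigraph holds exactly
#' `m * (n - 1)` edges before simplification. Self-loops are redrawn;
#' multi-edges are collapsed; each surviving undirected edge is then oriented
#' in a uniformly random direction (never both), yielding a binary directed
#' adjacency matrix with `a[i, j] = 1` meaning a connection from presynaptic
#' node `j` to postsynaptic node `i`.
#'
#' The resulting total-degree distribution follows a shallow power law over
#' the sizes this package targets; see [fit_power_law()].
#'
#' @param n number of nodes (> m).
#' @param m edges contributed per added node (>= 1). The package default of
#'   `m = 3` is a calibration choice; see the package vignette.
#' @param seed integer seed.
#' @return object of class `"connectivity_graph"`: list with `n`, `m`,
#'   `adjacency` (n x n binary matrix, row = postsynaptic), and
#'   `n_multi_edges`, the pre-collapse multigraph edge count `m * (n - 1)`.
#' @examples
#' g <- scale_free_graph(90, m = 3, seed = 1)
#' fit_power_law(degree_total(g))
#' @export
scale_free_graph <- function(n, m = 3, seed = NULL) {
  if (m < 1) stopf("`m` must be >= 1")
  if (n <= m) stopf("`n` must exceed `m`")
  n <- as.integer(n); m <- as.integer(m)
  with_seed(seed, {
    targets <- integer(2L * m * (n - 1L))
    pos <- 0L
    pre <- integer(m * (n - 1L)); post <- integer(m * (n - 1L)); ne <- 0L
    for (v in seq_len(n - 1L)) {        # nodes 1..n-1 (0-based v)
      for (i in seq_len(m)) {
        if (pos == 0L) {
          b <- 0L
        } else {
          repeat {
            b <- targets[sample.int(pos, 1L)]
            if (b != v) break
          }
        }
        targets[pos + 1L] <- v; targets[pos + 2L] <- b
        pos <- pos + 2L
        ne <- ne + 1L; pre[ne] <- v; post[ne] <- b
      }
    }
    und <- unique(cbind(pmin(pre, post), pmax(pre, post)))
    flip <- runif(nrow(und)) < 0.5
    from <- ifelse(flip, und[, 1], und[, 2]) + 1L   # presynaptic
    to   <- ifelse(flip, und[, 2], und[, 1]) + 1L   # postsynaptic
    adj <- matrix(0L, n, n)
    adj[cbind(to, from)] <- 1L
    structure(list(n = n, m = m, adjacency = adj,
                   n_multi_edges = m * (n - 1L)),
              class = "connectivity_graph")
  })
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity_graph> %d nodes, %d directed edges (m = %d)\n",
              x$n, sum(x$adjacency), x$m))
  invisible(x)
}

#' Total, in- and out-degrees of a connectivity graph
#'
#' `a[i, j] = 1` is an edge j -> i, so in-degree is the row sum and
#' out-degree the column sum; total degree is their sum.
#'
#' @param graph a [scale_free_graph()] result.
#' @return integer vector of length `n`.
#' @export
degree_total <- function(graph) {
  as.integer(rowSums(graph$adjacency) + colSums(graph$adjacency))
}

#' @rdname degree_total
#' @export
degree_in <- function(graph) as.integer(rowSums(graph$adjacency))

#' @rdname degree_total
#' @export
degree_out <- function(graph) as.integer(colSums(graph$adjacency))

#' Assign normally distributed synaptic weights to a graph
#'
#' Weight magnitudes are i.i.d. Normal(`mean`, `sd`) draws, redrawn while
#' non-positive, placed exactly on the support of the adjacency matrix.
#' Columns belonging to inhibitory presynaptic neurons are negated (a
#' Dale-like sign convention: a fast-spiking neuron hyperpolarizes all of its
#' targets).
#'
#' @param graph a [scale_free_graph()] result.
#' @param mean,sd weight magnitude distribution (defaults 10 and 3.5).
#' @param inhibitory integer ids of inhibitory presynaptic neurons.
#' @param seed integer seed.
#' @return numeric `n x n` matrix (class `"synaptic_matrix"`), row =
#'   postsynaptic, with attribute `inhibitory`.
#' @export
assign_weights <- function(graph, mean = 10, sd = 3.5,
                           inhibitory = integer(0), seed = NULL) {
  if (sd < 0) stopf("`sd` must be nonnegative")
  inhibitory <- as.integer(inhibitory)
  if (length(inhibitory) && (min(inhibitory) < 1 || max(inhibitory) > graph$n))
    stopf("`inhibitory` ids must lie in 1..n")
  with_seed(seed, {
    idx <- which(graph$adjacency == 1L)
    w <- rnorm(length(idx), mean, sd)
    while (any(bad <- w <= 0)) w[bad] <- rnorm(sum(bad), mean, sd)
    S <- matrix(0, graph$n, graph$n)
    S[idx] <- w
    if (length(inhibitory)) S[, inhibitory] <- -S[, inhibitory]
    attr(S, "inhibitory") <- inhibitory
    class(S) <- c("synaptic_matrix", class(S))
    S
  })
}

#' Fit a power law to a degree distribution
#'
#' Least-squares regression of `log(count)` on `log(degree)` over the
#' non-empty bins of the raw degree histogram (one bin per distinct positive
#' degree value). This histogram-regression convention deliberately keeps the
#' sparse high-degree tail bins, which is what produces the shallow exponents
#' characteristic of small scale-free networks; it is not a maximum-likelihood
#' tail estimator.
#'
#' @param degrees integer vector of node degrees.
#' @return object of class `"power_law_fit"`: list with `gamma` (the signed
#'   slope, i.e. the exponent of `P(m) ~ m^gamma`), `intercept`, `r_squared`,
#'   and `fit_degree_range`.
#' @examples
#' deg <- rep(1:20, times = round(1000 * (1:20)^-2))
#' fit_power_law(deg)$gamma  # close to -2
#' @export
fit_power_law <- function(degrees) {
  degrees <- degrees[degrees > 0]
  tb <- table(degrees)
  if (length(tb) < 3L)
    stopf("degree distribution is not fittable: need >= 3 distinct positive degrees")
  x <- log(as.numeric(names(tb)))
  y <- log(as.numeric(tb))
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(gamma = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 fit_degree_range = range(as.numeric(names(tb)))),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> gamma = %.3f (r^2 = %.3f, degrees %g..%g)\n",
              x$gamma, x$r_squared, x$fit_degree_range[1],
              x$fit_degree_range[2]))
  invisible(x)
}

#' Average fitted degree exponent over repeated graph generations
#'
#' Convenience wrapper: generates `n_seeds` graphs (seeds `seed_base + 1:k`),
#' fits [fit_power_law()] to the total-degree distribution of each, and
#' returns the per-seed exponents.
#'
#' @param n network size.
#' @param m edges per added node.
#' @param n_seeds number of generations.
#' @param seed_base seeds used are `seed_base + 1:n_seeds`.
#' @return numeric vector of fitted exponents.
#' @export
degree_exponents <- function(n, m = 3, n_seeds = 20, seed_base = 0) {
  vapply(seq_len(n_seeds), function(k) {
    g <- scale_free_graph(n, m, seed = seed_base + k)
    fit_power_law(degree_total(g))$gamma
  }, numeric(1))
}

#' Write / read a weighted graph as an edge-list TSV
#'
#' Format: `pre<TAB>post<TAB>weight` with a header, plus a JSON sidecar
#' (same path with extension `.json`) recording `n` and `m`.
#'
#' @param weights a [assign_weights()] matrix.
#' @param graph the generating [scale_free_graph()] (for `n`, `m`).
#' @param path output TSV path.
#' @export
write_graph_tsv <- function(weights, graph, path) {
  idx <- which(weights != 0, arr.ind = TRUE)
  df <- data.frame(pre = idx[, 2], post = idx[, 1],
                   weight = weights[idx])
  df <- df[order(df$pre, df$post), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n = graph$n, m = graph$m),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}
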
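#' Build a heterogeneous population of Izhikevich neurons
#'
#' Draws per-neuron parameters for a mixed population of regular-spiking (RS,
#' excitatory) and fast-spiking (FS, inhibitory) Izhikevich neurons. Each
#' neuron gets an independent heterogeneity draw r ~ U(0, 1) and its
#' `(a, b, c, d)` quadruple follows the standard RS/FS parameterization:
#'
#' * excitatory: `a = 0.02`, `b = 0.2`, `c = -65 + 15 r^2`, `d = 8 - 6 r^2`
#'   (classic RS at r = 0, grading towards bursting phenotypes at r = 1)
#' * inhibitory: `a = 0.02 + 0.08 r`, `b = 0.25 - 0.05 r`, `c = -65`, `d = 2`
#'
#' @param n number of neurons (>= 1).
#' @param frac_inhibitory fraction of FS inhibitory neurons; exactly
#'   `round(n * frac_inhibitory)` neurons are inhibitory, at uniformly random
#'   positions. Default 0.25 (the 75/25 RS/FS split found in cortical
#'   cultures).
#' @param seed integer seed for reproducible draws, or `NULL` to use the
#'   current RNG stream.
#' @return A data frame of class `"neuron_population"` with one row per
#'   neuron and columns `a`, `b`, `c`, `d`, `is_inhibitory`, `r`.
#' @examples
#' pop <- neuron_population(10, seed = 1)
#' table(pop$is_inhibitory)
#' @export
neuron_population <- function(n, frac_inhibitory = 0.25, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stopf("`n` must be a positive integer")
  n <- as.integer(n)
  check_scalar(frac_inhibitory, "frac_inhibitory", 0, 1)
  with_seed(seed, {
    n_inh <- round(n * frac_inhibitory)
    inhibitory <- rep(FALSE, n)
    if (n_inh > 0) inhibitory[sample.int(n, n_inh)] <- TRUE
    r <- runif(n)
    pop <- data.frame(
      a = ifelse(inhibitory, 0.02 + 0.08 * r, 0.02),
      b = ifelse(inhibitory, 0.25 - 0.05 * r, 0.2),
      c = ifelse(inhibitory, -65, -65 + 15 * r^2),
      d = ifelse(inhibitory, 2, 8 - 6 * r^2),
      is_inhibitory = inhibitory,
      r = r
    )
    class(pop) <- c("neuron_population", "data.frame")
    pop
  })
}

#' @export
print.neuron_population <- function(x, ...) {
  cat(sprintf("<neuron_population> %d neurons (%d excitatory RS, %d inhibitory FS)\n",
              nrow(x), sum(!x$is_inhibitory), sum(x$is_inhibitory)))
  invisible(x)
}

#' Parameters of the Ornstein-Uhlenbeck background noise current
#'
#' Each neuron receives an independent mean-reverting Gaussian noise current
#' with stationary mean `m_I`, stationary standard deviation `s_I` and
#' correlation length `tau_I`, integrated by the Euler-Maruyama recursion
#' `I <- I - (I/tau_I) dt + (m_I/tau_I) dt + s_I sqrt(2 dt / tau_I) xi`
#' with `xi` standard normal.
#'
#' @param tau_I correlation length (ms), > 0.
#' @param m_I stationary mean (model current units, labelled pA).
#' @param s_I stationary standard deviation (pA), >= 0.
#' @return list of class `"noise_params"`.
#' @export
noise_params <- function(tau_I = 1, m_I = 25, s_I = 9) {
  if (tau_I <= 0) stopf("`tau_I` must be positive")
  if (s_I < 0) stopf("`s_I` must be nonnegative")
  structure(list(tau_I = tau_I, m_I = m_I, s_I = s_I), class = "noise_params")
}

#' One Euler-Maruyama step of the Ornstein-Uhlenbeck noise current
#'
#' Vectorized over `I` and `xi`.
#'
#' @param I current value(s) (pA).
#' @param params a [noise_params()] object.
#' @param dt time step (ms), > 0.
#' @param xi standard-normal draw(s); drawn from the session RNG if missing.
#' @return updated current value(s).
#' @examples
#' ou_noise_step(25, noise_params(s_I = 0), dt = 0.1, xi = 0)  # fixed point
#' @export
ou_noise_step <- function(I, params = noise_params(), dt = 0.1,
                          xi = rnorm(length(I))) {
  if (!inherits(params, "noise_params")) params <- do.call(noise_params, params)
  if (dt <= 0) stopf("`dt` must be positive")
  I - (I / params$tau_I) * dt + (params$m_I / params$tau_I) * dt +
    params$s_I * sqrt(2 * dt / params$tau_I) * xi
}

#' Simulate a long Ornstein-Uhlenbeck noise path
#'
#' Iterates the same recursion as the network simulator (compiled path),
#' mainly for stationarity diagnostics.
#'
#' @param n_steps number of iterates.
#' @param params a [noise_params()] object.
#' @param dt time step (ms).
#' @param I0 initial value; defaults to the stationary mean.
#' @param seed integer seed.
#' @return numeric vector of `n_steps` iterates.
#' @export
ou_noise_path <- function(n_steps, params = noise_params(), dt = 0.1,
                          I0 = params$m_I, seed = 1) {
  if (!inherits(params, "noise_params")) params <- do.call(noise_params, params)
  ou_path_cpp(I0, as.integer(n_steps), dt, params$tau_I, params$m_I,
              params$s_I, as.numeric(seed))
}
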
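test_that("neuron population honours the RS/FS parameter families", {
  pop <- neuron_population(200, frac_inhibitory = 0.25, seed = 11)
  expect_equal(sum(pop$is_inhibitory), 50)
  expect_true(all(pop$r >= 0 & pop$r <= 1))
  exc <- pop[!pop$is_inhibitory, ]
  inh <- pop[pop$is_inhibitory, ]
  expect_equal(exc$a, rep(0.02, nrow(exc)))
  expect_equal(exc$b, rep(0.2, nrow(exc)))
  expect_equal(exc$c, -65 + 15 * exc$r^2)
  expect_equal(exc$d, 8 - 6 * exc$r^2)
  expect_equal(inh$a, 0.02 + 0.08 * inh$r)
  expect_equal(inh$b, 0.25 - 0.05 * inh$r)
  expect_equal(inh$c, rep(-65, nrow(inh)))
  expect_equal(inh$d, rep(2, nrow(inh)))
  # endpoint checks of the families: classic RS at r = 0, r = 1, FS at r = 0.5
  expect_equal(c(0.02, 0.2, -65 + 15 * 0, 8 - 6 * 0), c(0.02, 0.2, -65, 8))
  expect_equal(c(-65 + 15 * 1, 8 - 6 * 1), c(-50, 2))
  expect_equal(c(0.02 + 0.08 * 0.5, 0.25 - 0.05 * 0.5), c(0.06, 0.225))
  # reproducibility
  expect_identical(pop, neuron_population(200, 0.25, seed = 11))
  expect_error(neuron_population(0), "positive")
})

test_that("the OU step matches the printed Euler-Maruyama recursion", {
  p <- noise_params(tau_I = 2, m_I = 25, s_I = 9)
  xi <- 0.7
  got <- ou_noise_step(12, p, dt = 0.1, xi = xi)
  expect_equal(got, 12 - (12 / 2) * 0.1 + (25 / 2) * 0.1 +
                 9 * sqrt(2 * 0.1 / 2) * xi)
  # the stationary mean is a fixed point of the noiseless recursion
  expect_equal(ou_noise_step(25, noise_params(s_I = 0), dt = 0.1, xi = 0), 25)
  expect_error(noise_params(tau_I = 0), "positive")
})

test_that("long OU paths reach the recursion's stationary moments", {
  p <- ou_noise_path(1e6, seed = 3)
  # AR(1) with phi = 1 - dt/tau: exact stationary sd of the recursion
  phi <- 1 - 0.1 / 1
  sd_exact <- 9 * sqrt(2 / (2 - 0.1))
  n_eff <- 1e6 * (1 - phi) / (1 + phi)
  se_mean <- sd_exact * sqrt((1 + phi) / (1 - phi) / 1e6)
  se_sd <- sd_exact / sqrt(2 * n_eff)
  expect_lt(abs(mean(p) - 25), 3 * se_mean)
  expect_lt(abs(sd(p) - sd_exact), 3 * se_sd)
})

test_that("a subthreshold neuron sits exactly at the analytic fixed point", {
  # 0.04 v^2 + 5 v + 140 - u = 0 and b v = u at v = -70, b = 0.2
  pop <- data.frame(a = 0.02, b = 0.2, c = -65, d = 8,
                    is_inhibitory = FALSE, r = 0)
  class(pop) <- c("neuron_population", "data.frame")
  cfg <- sim_config(1, duration = 10, dt = 0.1, seed = 1,
                    noise = noise_params(m_I = 0, s_I = 0))
  st <- structure(list(v = -70, u = -14, I_noise = 0, t = 0),
                  class = "network_state")
  out <- step_network(st, pop, matrix(0, 1, 1), cfg, n_steps = 50)
  expect_equal(out$state$v, -70)
  expect_equal(out$state$u, -14)
  expect_length(out$fired, 0)
})

test_that("a neuron at the spike cut-off fires and resets to (c, u + d)", {
  pop <- data.frame(a = 0.02, b = 0.2, c = -65, d = 8,
                    is_inhibitory = FALSE, r = 0)
  class(pop) <- c("neuron_population", "data.frame")
  cfg <- sim_config(1, duration = 1, dt = 0.1, seed = 1,
                    noise = noise_params(m_I = 0, s_I = 0))
  st <- structure(list(v = 40, u = 0, I_noise = 0, t = 0),
                  class = "network_state")
  out <- step_network(st, pop, matrix(0, 1, 1), cfg)
  expect_equal(out$fired, 1L)
  expect_equal(out$state$v, -65)
  expect_equal(out$state$u, 8)
})

test_that("tonic spiking under constant drive matches a reference integration", {
  # independent plain-R Euler integration of the same scheme
  ref_rate <- local({
    v <- -65; u <- 0.2 * v; n_sp <- 0; dt <- 0.1
    for (k in seq_len(20000)) {            # 2 s
      if (v >= 40) { n_sp <- n_sp + 1; v <- -65; u <- u + 8; next }
      vn <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + 10)
      u <- u + dt * 0.02 * (0.2 * v - u)
      v <- vn
    }
    n_sp / 2
  })
  pop <- data.frame(a = 0.02, b = 0.2, c = -65, d = 8,
                    is_inhibitory = FALSE, r = 0)
  class(pop) <- c("neuron_population", "data.frame")
  cfg <- sim_config(1, duration = 2000, dt = 0.1, seed = 1,
                    noise = noise_params(m_I = 10, s_I = 0))
  st <- structure(list(v = -65, u = 0.2 * -65, I_noise = 10, t = 0),
                  class = "network_state")
  out <- step_network(st, pop, matrix(0, 1, 1), cfg, n_steps = 20000)
  sim_rate <- nrow(out$spikes) / 2
  expect_equal(sim_rate, ref_rate, tolerance = 0.05)
})

test_that("identical seeds give bit-identical rasters", {
  cfg <- sim_config(30, duration = 3000, seed = 5)
  expect_identical(run_simulation(cfg), run_simulation(cfg))
  r2 <- run_simulation(sim_config(30, duration = 3000, seed = 6))
  expect_false(identical(run_simulation(cfg), r2))
})

test_that("a zero-weight network decouples into independent neurons", {
  n <- 6
  pop <- neuron_population(n, 0.25, seed = 21)
  cfg <- sim_config(n, duration = 2000, seed = 21)
  full <- run_simulation(cfg, pop, matrix(0, n, n))
  solo <- do.call(rbind, lapply(seq_len(n), function(i) {
    ci <- sim_config(1, duration = 2000, seed = 21)
    ri <- run_simulation(ci, pop[i, , drop = FALSE], matrix(0, 1, 1),
                         stream_ids = i - 1L)
    if (nrow(ri)) data.frame(neuron = i, time = ri$time) else NULL
  }))
  solo <- solo[order(solo$time, solo$neuron), ]
  expect_equal(full$neuron, solo$neuron)
  expect_equal(full$time, solo$time)
})

test_that("population firing rate is nondecreasing in the noise mean", {
  rates <- vapply(c(15, 25, 35), function(mi) {
    cfg <- sim_config(20, duration = 5000, seed = 8,
                      noise = noise_params(m_I = mi, s_I = 9))
    r <- run_simulation(cfg)
    nrow(r) / 20 / 5
  }, 0)
  expect_true(all(diff(rates) >= 0))
})

test_that("the divergence guard names the offending neuron and time", {
  pop <- data.frame(a = 0.02, b = 0.2, c = -65, d = 8,
                    is_inhibitory = FALSE, r = 0)
  class(pop) <- c("neuron_population", "data.frame")
  cfg <- sim_config(1, duration = 100, dt = 0.1, seed = 1, guard = 100,
                    noise = noise_params(m_I = 1e5, s_I = 0))
  st <- structure(list(v = -65, u = -13, I_noise = 1e5, t = 0),
                  class = "network_state")
  expect_error(step_network(st, pop, matrix(0, 1, 1), cfg, n_steps = 100),
               "divergence: neuron 1")
})

test_that("spike rasters survive a TSV round trip", {
  cfg <- sim_config(10, duration = 1000, seed = 2)
  r <- run_simulation(cfg)
  path <- tempfile(fileext = ".tsv")
  write_raster(r, path)
  r2 <- read_raster(path)
  expect_equal(attr(r2, "n_neurons"), attr(r, "n_neurons"))
  expect_equal(attr(r2, "duration"), attr(r, "duration"))
  expect_equal(r2$neuron, r$neuron)
  expect_equal(r2$time, r$time, tolerance = 1e-6)
  unlink(path)
})
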
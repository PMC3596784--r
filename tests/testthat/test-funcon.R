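test_that("pairwise lags pick the nearest partner onset within the window", {
  oj <- c(1, 2, 3)
  # k fires exactly 100 ms after every j onset
  expect_equal(pairwise_lags(oj, oj + 0.1), rep(0.1, 3))
  # nothing within 500 ms of any j onset -> empty
  expect_length(pairwise_lags(c(1, 5, 9), c(1, 5, 9) + 0.8), 0)
  expect_length(pairwise_lags(numeric(0), oj), 0)
  # nearest, signed
  expect_equal(pairwise_lags(2, c(1.7, 2.4)), -0.3)
})

test_that("independent Poisson pairs yield near-uniform lag distributions", {
  ok <- vapply(1:100, function(s) {
    set.seed(2000 + s)
    a <- sort(runif(60, 0, 600)); b <- sort(runif(60, 0, 600))
    lg <- pairwise_lags(a, b)
    length(lg) < 5 ||
      suppressWarnings(ks.test(lg, "punif", -0.5, 0.5)$p.value) > 0.05
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("the dual statistical gate decides edge direction correctly", {
  set.seed(88)
  # consistent positive lags -> j leads k
  lg <- rep(0.1, 20) + rnorm(20, 0, 1e-6)
  expect_equal(test_direction(lg)$decision, "jk")
  expect_equal(test_direction(-lg)$decision, "kj")
  # synchronous pairs (zero-mean Gaussian) are rejected at about rate alpha
  dec <- vapply(1:200, function(s) {
    set.seed(s)
    test_direction(rnorm(200, 0, 0.05))$decision
  }, "")
  expect_lte(mean(dec != "none"), 0.05 + 0.03)
  # uncorrelated pairs (uniform lags) are rejected by the KS gate
  dec_u <- vapply(1:200, function(s) {
    set.seed(5000 + s)
    test_direction(runif(200, -0.5, 0.5))$decision
  }, "")
  expect_lte(mean(dec_u != "none"), 0.05 + 0.03)
  # fewer than 5 lags -> insufficient data
  d <- test_direction(c(0.1, 0.1, 0.1))
  expect_equal(d$decision, "none")
  expect_true(d$insufficient)
})

test_that("a feed-forward chain is recovered with no reversed edges", {
  hits <- 0; reversed <- 0; total <- 0
  for (s in 1:10) {
    ch <- make_chain_population(n_stages = 5, delay_ms = 120, jitter_ms = 10,
                                n_repetitions = 50, seed = s)
    g <- build_functional_graph(ch$onsets)
    truth <- paste(ch$truth$from, ch$truth$to)
    got <- paste(g$edges$from, g$edges$to)
    rev <- paste(ch$truth$to, ch$truth$from)
    hits <- hits + sum(truth %in% got)
    reversed <- reversed + sum(rev %in% got)
    total <- total + length(truth)
  }
  expect_gte(hits / total, 0.9)
  expect_equal(reversed, 0)
})

test_that("time reversal reverses every inferred edge", {
  ch <- make_chain_population(n_stages = 4, seed = 3)
  g <- build_functional_graph(ch$onsets)
  rev_onsets <- onset_series(lapply(ch$onsets$onsets,
                                    function(x) ch$onsets$duration - x),
                             ch$onsets$duration)
  g_rev <- build_functional_graph(rev_onsets)
  key <- function(e) sort(paste(e$from, e$to))
  expect_equal(key(g_rev$edges),
               sort(paste(g$edges$to, g$edges$from)))
})

test_that("independent populations stay near the nominal false-positive rate", {
  dens <- vapply(1:20, function(s) {
    pop <- make_poisson_population(10, 0.1, 600, seed = 300 + s)
    g <- build_functional_graph(pop)
    nrow(g$edges) / choose(10, 2)
  }, 0)
  expect_lte(mean(dens), 0.05 + 0.02)
})

test_that("node ranking orders hubs first with documented tie-breaks", {
  # star: node 1 drives 2..6
  star <- onset_series(c(list(seq(1, 50)),
                         lapply(2:6, function(i) seq(1, 50) + 0.1)), 60)
  g <- build_functional_graph(star)
  expect_equal(rank_nodes(g, "output")[1], 1)
  expect_false(1 %in% rank_nodes(g, "input"))
  # chain end points differ between input and output rankings
  ch <- make_chain_population(n_stages = 3, jitter_ms = 5, seed = 1)
  gc <- build_functional_graph(ch$onsets)
  expect_false(3 %in% rank_nodes(gc, "output"))
  expect_false(1 %in% rank_nodes(gc, "input"))
  # empty graph -> empty ranking
  g0 <- build_functional_graph(make_poisson_population(3, 0.01, 50, seed = 1),
                               min_lags = 1e6)
  expect_length(rank_nodes(g0, "input"), 0)
})

test_that("cross-correlation matches a naive double-loop oracle", {
  set.seed(55)
  worst <- 0
  for (q in 1:100) {
    a <- as.numeric(runif(200) < 0.1)
    b <- as.numeric(runif(200) < 0.1)
    if (sd(a) == 0 || sd(b) == 0) next
    got <- cross_correlation(a, b, max_lag_samples = 25)
    ref <- naive_cross_correlation(a, b, 25)
    worst <- max(worst, max(abs(got$cc - ref)))
    # CC_ab(tau) = CC_ba(-tau), exactly
    ba <- cross_correlation(b, a, max_lag_samples = 25)
    expect_identical(got$cc, rev(ba$cc))
  }
  expect_lt(worst, 1e-12)
})

test_that("autocorrelation and pure delays have exact correlation signatures", {
  set.seed(77)
  a <- as.numeric(runif(300) < 0.2)
  auto <- cross_correlation(a, a, max_lag_samples = 30)
  expect_equal(auto$cc_max, 1)
  expect_equal(auto$tau_max, 0)
  expect_true(all(abs(auto$cc) <= 1 + 1e-12))
  # b repeats a 10 samples later: a leads, tau_max positive
  b <- c(rep(0, 10), a[1:290])
  del <- cross_correlation(a, b, max_lag_samples = 30)
  expect_equal(del$tau_max, 10)
  expect_error(cross_correlation(a, rep(0, 300), max_lag_samples = 5),
               "zero variance")
})

test_that("correlation summaries respect the leads-positive convention", {
  # two identical neurons
  on <- onset_series(list(c(1, 3, 5, 7), c(1, 3, 5, 7)), 10)
  sm <- summarize_correlations(on)
  expect_equal(sm$cc_max_mean, c(1, 1))
  expect_equal(sm$tau_max_mean, c(0, 0))
  # three-stage chain: first neuron leads (positive), last lags (negative)
  ch <- make_chain_population(n_stages = 3, jitter_ms = 0, seed = 2)
  smc <- summarize_correlations(ch$onsets)
  expect_gt(smc$tau_max_mean[1], 0)
  expect_lt(smc$tau_max_mean[3], 0)
})

test_that("an early-recruited subgroup separates on the lag axis", {
  set.seed(123)
  # neurons 1-4 fire 200 ms before neurons 5-12 in every sweep
  starts <- seq(1, 240, by = 6)
  on <- c(lapply(1:4, function(i) starts + rnorm(length(starts), 0, 0.01)),
          lapply(5:12, function(i) starts + 0.2 + rnorm(length(starts), 0, 0.01)))
  on <- onset_series(lapply(on, sort), 245)
  sm <- summarize_correlations(on)
  expect_true(all(sm$tau_max_mean[1:4] > 0))
  expect_true(all(sm$tau_max_mean[5:12] < sm$tau_max_mean[1:4][1]))
  expect_gt(min(sm$tau_max_mean[1:4]) - max(sm$tau_max_mean[5:12]), 0.05)
})
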
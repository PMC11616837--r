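test_that("forward-Euler integration matches an inline reference loop", {
  prm <- izhikevich_params()
  sim <- simulate_izhikevich(prm, duration = 1000, I = 10)
  expect_gte(length(sim$spike_times), 1L)
  expect_true(all(sim$v <= 30))

  # independent plain-R reference of the same scheme
  v_ref <- numeric(1000); u_ref <- numeric(1000)
  vi <- -65; ui <- 0.2 * -65
  for (i in 1:1000) {
    if (vi >= 30) {
      v_ref[i] <- 30; vi <- prm$c; ui <- ui + prm$d; u_ref[i] <- ui
      next
    }
    v_ref[i] <- vi; u_ref[i] <- ui
    vi2 <- vi + (0.04 * vi^2 + 5 * vi + 140 - ui + 10)
    ui <- ui + prm$a * (prm$b * vi - ui)
    vi <- vi2
  }
  expect_equal(sim$v, v_ref, tolerance = 1e-12)
  expect_equal(sim$u, u_ref, tolerance = 1e-12)
})

test_that("the neuron is silent and bounded at rest without input", {
  sim <- simulate_izhikevich(izhikevich_params(), duration = 2000, I = 0)
  expect_length(sim$spike_times, 0L)
  expect_true(all(sim$v > -80 & sim$v < 0))
})

test_that("the after-spike reset stores 30 mV then jumps to c with u + d", {
  prm <- izhikevich_params(v0 = 35, u0 = 1)
  sim <- simulate_izhikevich(prm, duration = 3, I = 0)
  expect_equal(sim$v[1], 30)
  expect_equal(sim$spike_times[1], 0)
  expect_equal(sim$v[2], prm$c)
  expect_equal(sim$u[1], 1 + prm$d)
})

test_that("halving dt changes subthreshold trajectories by under 1%", {
  p1 <- izhikevich_params(dt = 0.25)
  p2 <- izhikevich_params(dt = 0.125)
  s1 <- simulate_izhikevich(p1, duration = 500, I = 2)  # subthreshold drive
  s2 <- simulate_izhikevich(p2, duration = 500, I = 2)
  expect_length(s1$spike_times, 0L)
  expect_length(s2$spike_times, 0L)
  v2_at_ms <- s2$v[seq(1, length(s2$v), by = 2)]
  rng <- diff(range(s1$v))
  expect_lt(max(abs(s1$v - v2_at_ms)) / rng, 0.01)
})

test_that("transduction limits behave as constructed", {
  x <- with_seed_local(3, rnorm(2000, sd = 10))
  flat <- transduce(x, transduction_model(gain = 0, noise_sd = 0,
                                          offset = 1.7, advance_ms = 0))
  expect_equal(unique(flat), 1.7)

  ident <- transduction_model(gain = 1, tau = 1e-6, saturation = 1e6,
                              offset = 0, noise_sd = 0, advance_ms = 0)
  y <- transduce(x, ident)
  expect_lt(max(abs(y - x)) / diff(range(x)), 0.01)

  sim <- simulate_izhikevich(izhikevich_params(), 5000, I = 10)
  out <- transduce(sim$v, transduction_model(), seed = 1)
  expect_lt(sd(out), 0.1 * sd(sim$v))
})

test_that("cross-correlation lag recovers constructed shifts exactly", {
  x <- with_seed_local(5, as.numeric(arima.sim(list(ar = 0.9), 3000)))
  shift_by <- function(x, k) {   # y_t = x_{t+k} padded at the tail
    n <- length(x)
    if (k >= 0) c(x[(k + 1):n], rep(x[n], k)) else
      c(rep(x[1], -k), x[1:(n + k)])
  }
  for (k in -5:5) {
    y <- shift_by(x, k)
    expect_equal(cross_correlation_lag(x, y, max_lag = 10)$lag, -k)
  }
  expect_equal(cross_correlation_lag(x, x, max_lag = 10)$lag, 0)
  expect_error(cross_correlation_lag(x, rep(1, 3000), 10),
               "zero-variance")
})

test_that("Welch t follows its closed form and is antisymmetric", {
  expect_equal(welch_t(1, 1, 100, 1, 1, 100)$t, 0)
  expect_equal(welch_t(1, 1, 100, 0, 1, 100)$t, 7.0711,
               tolerance = 1e-4)
  a <- welch_t(3.2, 1.4, 50, -1.1, 2.7, 80)
  b <- welch_t(-1.1, 2.7, 80, 3.2, 1.4, 50)
  expect_equal(a$t, -b$t)
  expect_equal(a$p_value, b$p_value)
  expect_error(welch_t(1, 0, 10, 2, 0, 10), "zero pooled variance")
})

test_that("the KS statistic and p-value match the reference implementation", {
  expect_equal(ks_two_sample(1:10, 1:10)$statistic, 0)
  expect_equal(ks_two_sample(1:10, 101:110)$statistic, 1)
  x <- with_seed_local(6, rnorm(500))
  y <- with_seed_local(7, rnorm(400, mean = 0.2))
  ours <- ks_two_sample(x, y)
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("analyze_pair assembles consistent comparison statistics", {
  x <- with_seed_local(8, as.numeric(arima.sim(list(ar = 0.8), 5000)))
  self <- analyze_pair(x, x, dt = 1, max_lag_ms = 50)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$lag_ms, 0)
  expect_equal(self$ks$statistic, 0)
  expect_equal(self$welch$t, 0)

  a <- with_seed_local(9, rnorm(1e4))
  b <- with_seed_local(10, rnorm(1e4))
  indep <- analyze_pair(a, b, dt = 1, max_lag_ms = 10)
  expect_lt(abs(indep$pearson_r), 0.03)

  # Pearson r invariant under positive affine rescaling of one signal
  scaled <- analyze_pair(x, 3.7 * x + 12, dt = 1, max_lag_ms = 10)
  expect_equal(scaled$pearson_r, 1, tolerance = 1e-12)
})

test_that("a transduction advance of 122 ms appears as a -122 ms lag", {
  pair <- generate_signal_pair(
    transduction = transduction_model(tau = 1e-6, noise_sd = 0.02,
                                      advance_ms = 122),
    duration = 2e4, seed = 12)
  res <- analyze_pair(pair$input, pair$output, dt = pair$dt,
                      max_lag_ms = 300)
  expect_lte(abs(res$lag_ms - (-122)), 2 * pair$dt)
})
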
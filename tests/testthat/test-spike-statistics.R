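test_that("summarize reproduces the published amplitude block identities", {
  # quartile/min/max block of the 1.8 mg/ml amplitude statistics
  s <- summarize(c(0.38, 2.86, 4.96, 6.69, 15.01), units = "mV")
  expect_equal(s$peak_to_peak, 14.63)
  expect_equal(s$min, 0.38)
  expect_equal(s$max, 15.01)

  expect_equal(summarize(c(3, 4))$rms, sqrt(12.5), tolerance = 1e-6)

  one <- summarize(5)
  expect_equal(one$mean, 5)
  expect_equal(one$min, 5)
  expect_equal(one$max, 5)
  expect_equal(one$sd, 0)
  expect_true(one$degenerate)

  expect_error(summarize(numeric(0)), "empty")
})

test_that("summarize is permutation-invariant and order statistics are ordered", {
  for (seed in 1:5) {
    x <- with_seed_local(seed, rgamma(50, shape = 2))
    s1 <- summarize(x)
    s2 <- summarize(with_seed_local(seed + 100, sample(x)))
    expect_equal(s1[c("mean", "sd", "q1", "median", "q3", "rms")],
                 s2[c("mean", "sd", "q1", "median", "q3", "rms")])
    expect_true(s1$min <= s1$q1 && s1$q1 <= s1$median &&
                s1$median <= s1$q3 && s1$q3 <= s1$max)
    expect_equal(s1$peak_to_peak, s1$max - s1$min)
  }
})

test_that("plugin skewness and kurtosis match hand-computed values", {
  expect_equal(skewness(c(-1, 0, 1)), 0)
  expect_equal(skewness(c(0, 0, 0, 1)), 1.1547, tolerance = 1e-4)
  expect_equal(kurtosis(c(-1, 1, -1, 1)), 1)
  expect_equal(kurtosis(c(0, 0, 0, 1)), 2.3333, tolerance = 1e-4)
  expect_error(skewness(rep(2, 5)), "zero variance")
  expect_error(kurtosis(rep(2, 5)), "zero variance")
})

test_that("moment ratios have the right large-sample limits and invariances", {
  x <- with_seed_local(1, rgamma(1e6, shape = 4))
  expect_equal(skewness(x), 2 / sqrt(4), tolerance = 0.02)
  z <- with_seed_local(2, rnorm(1e6))
  expect_equal(kurtosis(z), 3, tolerance = 0.05)

  y <- with_seed_local(3, rexp(500))
  expect_equal(skewness(3 * y + 10), skewness(y), tolerance = 1e-12)
  expect_equal(kurtosis(3 * y + 10), kurtosis(y), tolerance = 1e-12)
  expect_equal(skewness(-y), -skewness(y), tolerance = 1e-12)
})

test_that("gamma_pdf evaluates the shape/scale density", {
  expect_equal(gamma_pdf(0.5, 1, 1), exp(-0.5), tolerance = 1e-6)
  expect_equal(gamma_pdf(1, 2, 1), exp(-1), tolerance = 1e-6)
  # mode at (shape - 1) * scale for shape > 1
  xs <- seq(0.01, 10, by = 0.001)
  d <- gamma_pdf(xs, shape = 3, scale = 1.2)
  expect_equal(xs[which.max(d)], (3 - 1) * 1.2, tolerance = 1e-2)
  expect_error(gamma_pdf(-1, 2, 1), "x > 0")
})

test_that("gamma MLE recovers parameters and satisfies its identities", {
  x <- with_seed_local(101, rgamma(1e5, shape = 32.27402, scale = 0.01904))
  fit <- fit_gamma_mle(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$shape - 32.27402) / 32.27402, 0.02)
  # first-moment identity of the profile MLE
  expect_equal(fit$shape * fit$scale, mean(x), tolerance = 1e-10)

  e <- with_seed_local(7, rexp(1e5))
  fe <- fit_gamma_mle(e)
  expect_equal(fe$shape, 1, tolerance = 0.02)

  # the MLE cannot be worse than the method-of-moments start
  y <- with_seed_local(9, rgamma(500, shape = 3, scale = 2))
  fy <- fit_gamma_mle(y)
  a0 <- mean(y)^2 / var(y)
  ll0 <- sum(dgamma(y, shape = a0, scale = mean(y) / a0, log = TRUE))
  expect_gte(fy$log_likelihood, ll0)

  expect_error(fit_gamma_mle(c(-1, rexp(20))), "positive")
  expect_error(fit_gamma_mle(rexp(5)), "n >= 10")
})

test_that("Scott bandwidth follows its closed form and scalings", {
  x <- with_seed_local(4, rnorm(100))
  s <- sd(x); iqr <- IQR(x, type = 7)
  expect_equal(scott_bandwidth(x),
               100^(-1 / 5) * 1.06 * min(s, iqr / 1.34),
               tolerance = 1e-12)
  # worked example: n = 100, sd = 1, IQR = 1.349
  xs <- (x - mean(x)) / s  # sd exactly 1
  h_ref <- 100^(-1 / 5) * 1.06 * min(1, IQR(xs, type = 7) / 1.34)
  expect_equal(scott_bandwidth(xs), h_ref)

  expect_equal(scott_bandwidth(5 * x), 5 * scott_bandwidth(x),
               tolerance = 1e-12)
  ns <- c(50, 500, 5000)
  hs <- vapply(ns, function(n)
    scott_bandwidth(with_seed_local(8, rnorm(n))), numeric(1))
  expect_true(all(diff(hs) < 0))
  expect_error(scott_bandwidth(rep(1, 10)), "degenerate")
})

test_that("the kernel density estimate is normalized and resolves modes", {
  k1 <- kde(0, bandwidth = 1, grid = 0)
  expect_equal(k1$density, 1 / sqrt(2 * pi), tolerance = 1e-6)

  x <- with_seed_local(5, rnorm(400, mean = 2, sd = 0.7))
  k <- kde(x)
  integral <- sum(diff(k$grid) *
                    (head(k$density, -1) + tail(k$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 0.01)
  expect_true(all(k$density >= 0))

  bi <- c(with_seed_local(6, rnorm(300, -3, 0.3)),
          with_seed_local(7, rnorm(300, 3, 0.3)))
  kb <- kde(bi, bandwidth = 0.3)
  d <- kb$density
  n_modes <- sum(d[2:(length(d) - 1)] > d[1:(length(d) - 2)] &
                 d[2:(length(d) - 1)] > d[3:length(d)] &
                 d[2:(length(d) - 1)] > max(d) / 4)
  expect_equal(n_modes, 2)
})

test_that("the Fano factor separates Poisson, periodic and gamma regimes", {
  po <- poisson_train(rate = 10, duration = 1e4, seed = 31)
  expect_equal(as.numeric(fano_factor(po, 1)), 1, tolerance = 0.05)

  # boundary windows contribute at most one off-count to a periodic train
  per <- generate_spike_train(periodic_process(5), 1, 1, 5000, seed = 1)
  expect_lt(as.numeric(fano_factor(per, 50)), 0.01)

  g2 <- generate_spike_train(gamma_renewal(2, 2), 1, 1, 4e4, seed = 13)
  expect_equal(as.numeric(fano_factor(g2, 100)), 0.5, tolerance = 0.05)

  # zero-count window case is flagged, not silently numeric
  sparse <- spike_train(numeric(0), numeric(0), 100)
  ff <- fano_factor(sparse, 10)
  expect_true(is.na(ff))
  expect_true(attr(ff, "undefined"))
  expect_error(fano_factor(po, 9000), "2 complete windows")
})
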
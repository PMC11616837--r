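#' Izhikevich neuron parameters
#'
#' The two-variable Izhikevich model: membrane potential `v` (mV) with
#' quadratic dynamics `dv/dt = 0.04 v^2 + 5 v + 140 - u + I`, recovery
#' variable `u` with `du/dt = a (b v - u)`, and the after-spike reset
#' `v <- c`, `u <- u + d` whenever `v` reaches the 30 mV threshold.
#'
#' @param a,b,c,d dimensionless model parameters; defaults are the
#'   regular-spiking cortical configuration (a = 0.02, b = 0.2, c = -65,
#'   d = 8).
#' @param v0 initial membrane potential, mV.
#' @param u0 initial recovery value; default `b * v0`.
#' @param dt integration step, ms.
#' @return object of class `izhikevich_params`.
#' @export
izhikevich_params <- function(a = 0.02, b = 0.2, c = -65, d = 8,
                              v0 = -65, u0 = b * v0, dt = 1) {
  stopifnot(dt > 0)
  structure(list(a = a, b = b, c = c, d = d, v0 = v0, u0 = u0, dt = dt),
            class = "izhikevich_params")
}

#' Simulate an Izhikevich neuron by forward Euler
#'
#' Integrates the model at fixed step `params$dt` (the canonical published
#' scheme for this model). Whenever the pre-step potential reaches 30 mV a
#' spike is recorded, the stored sample is clipped to 30 mV, and the state
#' is reset (`v <- c`, `u <- u + d`).
#'
#' @param params an [izhikevich_params()].
#' @param duration simulation length, ms.
#' @param I input current: a scalar, a vector with one entry per step, or
#'   a function of time (ms).
#' @return list with `times` (ms), `v` (mV, all stored values <= 30),
#'   `u`, `spike_times` (ms).
#' @examples
#' sim <- simulate_izhikevich(izhikevich_params(), duration = 1000, I = 10)
#' length(sim$spike_times)
#' @export
simulate_izhikevich <- function(params, duration, I = 10) {
  stopifnot(inherits(params, "izhikevich_params"), duration >= params$dt)
  dt <- params$dt
  n <- floor(duration / dt)
  times <- (seq_len(n) - 1) * dt
  I_vec <- if (is.function(I)) {
    vapply(times, I, numeric(1))
  } else if (length(I) == 1L) {
    rep(as.numeric(I), n)
  } else if (length(I) == n) {
    as.numeric(I)
  } else {
    stop(sprintf("I must be scalar, a function, or length %d", n),
         call. = FALSE)
  }
  v <- numeric(n)
  u <- numeric(n)
  vi <- params$v0
  ui <- params$u0
  spikes <- numeric(0)
  for (i in seq_len(n)) {
    if (vi >= 30) {
      spikes <- c(spikes, times[i])
      v[i] <- 30          # the pre-reset sample is stored clipped at 30 mV
      vi <- params$c
      ui <- ui + params$d
      u[i] <- ui
      next
    }
    v[i] <- vi
    u[i] <- ui
    dv <- 0.04 * vi^2 + 5 * vi + 140 - ui + I_vec[i]
    du <- params$a * (params$b * vi - ui)
    vi <- vi + dt * dv
    ui <- ui + dt * du
    if (!is.finite(vi) || !is.finite(ui)) {
      stop(sprintf("Izhikevich state diverged at step %d (t = %g ms)",
                   i, times[i]), call. = FALSE)
    }
  }
  list(times = times, v = v, u = u, spike_times = spikes)
}

#' Transduction stand-in for the proteinoid-chondroitin network
#'
#' A configurable signal transformation standing in for the attenuation
#' and modulation that the proteinoid-CS mixture applies to a driving
#' potential: first-order low-pass of `gain * input`, soft saturation
#' (tanh) at `saturation`, an optional time advance, plus `offset` and
#' Gaussian noise. It is an explicit stand-in, not a fitted model; the
#' defaults produce output on the scale of the published comparison
#' (output SD a few tenths of a mV against an input SD of ~20 mV, output
#' leading the input by 122 ms).
#'
#' @param gain dimensionless input gain.
#' @param tau low-pass time constant, ms (> 0).
#' @param saturation soft-saturation level, mV.
#' @param offset additive output offset, mV.
#' @param noise_sd output noise SD, mV.
#' @param advance_ms time advance of the output relative to the input, ms
#'   (positive values make output changes precede the input, yielding a
#'   negative cross-correlation lag).
#' @return object of class `transduction_model`.
#' @export
transduction_model <- function(gain = 0.02, tau = 5, saturation = 5,
                               offset = 2.3, noise_sd = 0.1,
                               advance_ms = 122) {
  stopifnot(tau > 0, noise_sd >= 0, saturation > 0, advance_ms >= 0)
  structure(list(gain = gain, tau = tau, saturation = saturation,
                 offset = offset, noise_sd = noise_sd,
                 advance_ms = advance_ms),
            class = "transduction_model")
}

#' Apply a transduction model to a signal
#'
#' @param input numeric input signal (mV), uniformly sampled.
#' @param model a [transduction_model()].
#' @param dt sample step of `input`, ms.
#' @param seed optional integer seed for the output noise.
#' @return numeric output signal, same length as `input`.
#' @export
transduce <- function(input, model, dt = 1, seed = NULL) {
  stopifnot(inherits(model, "transduction_model"), length(input) > 0,
            dt > 0)
  x <- model$gain * as.numeric(input)
  # first-order low-pass, exact discretization for a piecewise-constant input
  alpha <- 1 - exp(-dt / model$tau)
  y <- numeric(length(x))
  y[1L] <- x[1L]
  for (i in seq_along(x)[-1L]) {
    y[i] <- y[i - 1L] + alpha * (x[i] - y[i - 1L])
  }
  y <- model$saturation * tanh(y / model$saturation)
  shift <- round(model$advance_ms / dt)
  if (shift > 0) {
    # advance: output at t carries the filtered input at t + shift
    y <- c(y[-seq_len(shift)], rep(y[length(y)], shift))
  }
  y <- y + model$offset
  if (model$noise_sd > 0) {
    y <- with_seed(seed, y + stats::rnorm(length(y), sd = model$noise_sd))
  }
  y
}

#' Paired input/output thalamocortical-style signals
#'
#' Simulates an Izhikevich membrane potential (the "input", driven by a
#' constant current with Gaussian fluctuations) and passes it through a
#' [transduction_model()] (the "output"). With the defaults each signal
#' has 100,000 samples at 1 ms.
#'
#' @param neuron an [izhikevich_params()].
#' @param transduction a [transduction_model()].
#' @param duration simulation length, ms.
#' @param I_mean,I_sd mean and SD of the per-step driving current.
#' @param seed optional integer seed.
#' @return list with `times` (ms), `input` (mV), `output` (mV), `dt` (ms).
#' @export
generate_signal_pair <- function(neuron = izhikevich_params(),
                                 transduction = transduction_model(),
                                 duration = 1e5, I_mean = 10, I_sd = 2,
                                 seed = NULL) {
  stopifnot(duration > 0)
  with_seed(seed, {
    n <- floor(duration / neuron$dt)
    I <- I_mean + if (I_sd > 0) stats::rnorm(n, sd = I_sd) else 0
    sim <- simulate_izhikevich(neuron, duration, I = I)
    out <- transduce(sim$v, transduction, dt = neuron$dt)
    list(times = sim$times, input = sim$v, output = out, dt = neuron$dt)
  })
}

#' Cross-correlation lag between two signals
#'
#' Computes the Pearson correlation of `(x_t, y_{t + lag})` over the
#' overlapping samples for every integer lag in `[-max_lag, max_lag]` and
#' returns the lag maximizing it. A negative lag means the pattern in `y`
#' precedes the matching pattern in `x`.
#'
#' @param x,y equal-length numeric signals, length > `2 * max_lag`.
#' @param max_lag maximum |lag| scanned, in samples.
#' @return list with `lag` (samples, signed), `correlation` (at the
#'   maximizing lag), `lags`, `correlations` (the full scan).
#' @examples
#' x <- sin(seq(0, 20, by = 0.1))
#' cross_correlation_lag(x, c(x[-(1:5)], rep(0, 5)), max_lag = 10)$lag # -5
#' @export
cross_correlation_lag <- function(x, y, max_lag) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  stopifnot(length(x) == length(y), max_lag >= 0,
            length(x) > 2 * max_lag)
  lags <- seq.int(-max_lag, max_lag)
  n <- length(x)
  cors <- vapply(lags, function(l) {
    if (l >= 0) {
      xs <- x[seq_len(n - l)]
      ys <- y[seq_len(n - l) + l]
    } else {
      xs <- x[seq_len(n + l) - l]
      ys <- y[seq_len(n + l)]
    }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      stop("zero-variance overlap: correlation undefined", call. = FALSE)
    }
    stats::cor(xs, ys)
  }, numeric(1))
  best <- which.max(cors)
  list(lag = lags[best], correlation = cors[best],
       lags = lags, correlations = cors)
}

#' Welch two-sample t statistic from summary statistics
#'
#' `t = (mean_x - mean_y) / sqrt(sd_x^2 / n_x + sd_y^2 / n_y)` -- the
#' unequal-variance form, appropriate when the two signals' SDs differ by
#' orders of magnitude.
#'
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y group summary statistics
#'   (`n >= 2`, SDs nonnegative and not both zero).
#' @return list with `t`, `df` (Welch-Satterthwaite), `p_value`
#'   (two-sided).
#' @examples
#' welch_t(-37.413, 20.55, 1e5, 1.5487, 0.32952, 1e5)$t
#' @export
welch_t <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y) {
  stopifnot(n_x >= 2, n_y >= 2, sd_x >= 0, sd_y >= 0)
  if (sd_x == 0 && sd_y == 0) {
    stop("zero pooled variance: t undefined", call. = FALSE)
  }
  vx <- sd_x^2 / n_x
  vy <- sd_y^2 / n_y
  t <- (mean_x - mean_y) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic Kolmogorov series with the effective sample size
#' `n_x * n_y / (n_x + n_y)`.
#'
#' @param x,y non-empty numeric samples.
#' @return list with `statistic` (D, in `[0, 1]`) and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  x <- sort(as.numeric(x))
  y <- sort(as.numeric(y))
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  pooled <- sort(unique(c(x, y)))
  ex <- findInterval(pooled, x) / length(x)
  ey <- findInterval(pooled, y) / length(y)
  D <- max(abs(ex - ey))
  nx <- as.numeric(length(x))
  ny <- as.numeric(length(y))
  n_eff <- nx * ny / (nx + ny)
  lambda <- sqrt(n_eff) * D
  p <- if (lambda < 0.05) {
    1  # the alternating series is unusable this close to zero; Q -> 1
  } else {
    k <- 1:100
    2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  }
  list(statistic = D, p_value = min(max(p, 0), 1))
}

#' Full input/output signal comparison
#'
#' Assembles the signal-comparison battery for a paired recording:
#' per-signal [summarize()] blocks, Welch t on the sample statistics,
#' Pearson correlation, two-sample KS test, and the cross-correlation lag
#' converted to milliseconds.
#'
#' @param input,output equal-length signals, mV.
#' @param dt sample step, ms.
#' @param max_lag_ms maximum |lag| scanned, ms.
#' @return object of class `thalamocortical_result`: list with
#'   `input_stats`, `output_stats`, `welch` (`t`, `df`, `p_value`),
#'   `pearson_r`, `ks` (`statistic`, `p_value`), `lag_ms`,
#'   `lag_correlation`, `n`, `dt_ms`.
#' @export
analyze_pair <- function(input, output, dt = 1, max_lag_ms = 500) {
  input <- as.numeric(input)
  output <- as.numeric(output)
  stopifnot(length(input) == length(output), dt > 0)
  sx <- summarize(input, units = "mV")
  sy <- summarize(output, units = "mV")
  w <- welch_t(sx$mean, sx$sd, sx$n, sy$mean, sy$sd, sy$n)
  xc <- cross_correlation_lag(input, output,
                              max_lag = round(max_lag_ms / dt))
  structure(list(
    input_stats = sx, output_stats = sy, welch = w,
    pearson_r = stats::cor(input, output),
    ks = ks_two_sample(input, output),
    lag_ms = xc$lag * dt, lag_correlation = xc$correlation,
    n = length(input), dt_ms = dt),
    class = "thalamocortical_result")
}

#' @export
print.thalamocortical_result <- function(x, ...) {
  cat("thalamocortical_result\n")
  cat(sprintf("  input:  mean %.4f mV, sd %.5f mV, range [%.4f, %.4f]\n",
              x$input_stats$mean, x$input_stats$sd,
              x$input_stats$min, x$input_stats$max))
  cat(sprintf("  output: mean %.4f mV, sd %.5f mV, range [%.4f, %.4f]\n",
              x$output_stats$mean, x$output_stats$sd,
              x$output_stats$min, x$output_stats$max))
  cat(sprintf("  Welch t = %.4f (df %.0f, p = %.3g)\n",
              x$welch$t, x$welch$df, x$welch$p_value))
  cat(sprintf("  Pearson r = %.4f; KS D = %.4f (p = %.3g)\n",
              x$pearson_r, x$ks$statistic, x$ks$p_value))
  cat(sprintf("  lag at max cross-correlation: %g ms (r = %.4f)\n",
              x$lag_ms, x$lag_correlation))
  invisible(x)
}
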
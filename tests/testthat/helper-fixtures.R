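# shared fixture builders

# uniform 1 Hz trace from raw values
make_trace <- function(values, rate = 1) {
  voltage_trace((seq_along(values) - 1) / rate, values, units = "mV")
}

# homogeneous Poisson spike train (unit amplitudes)
poisson_train <- function(rate, duration, seed) {
  with_seed_local(seed, {
    isis <- stats::rexp(ceiling(rate * duration * 1.5 + 50), rate = rate)
    t <- cumsum(isis)
    while (t[length(t)] < duration) {
      t <- c(t, t[length(t)] +
               cumsum(stats::rexp(1000, rate = rate)))
    }
    t <- t[t <= duration]
    spike_train(t, rep(1, length(t)), duration)
  })
}

with_seed_local <- function(seed, expr) withr::with_seed(seed, expr)
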
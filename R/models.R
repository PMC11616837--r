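#' Point-process models for interspike intervals
#'
#' Constructors for the reference spike-train models used in the
#' Fano-factor comparison: renewal processes (gamma, inverse Gaussian,
#' shifted exponential with refractory period, periodic) and two
#' rate-switching count models (Markov-modulated Poisson, alternating
#' Poisson).
#'
#' @param shape gamma shape `k > 0`; `FF -> 1/k` at large windows.
#' @param rate event rate in 1/s (gamma: mean ISI = `shape / rate`).
#' @param mean mean ISI of the inverse Gaussian (s).
#' @param shape_ig inverse-Gaussian shape parameter (s);
#'   `FF -> mean / shape_ig`.
#' @param refractory absolute refractory period added to exponential ISIs
#'   (s).
#' @param p per-interval switch probability of the Markov-modulated
#'   process, or the base rate of the alternating process (1/s).
#' @param rates length-2 vector of Poisson rates for the two Markov states
#'   (1/s).
#' @param factor rate ratio of the alternating process: rates alternate
#'   between `p` and `p * factor` on successive intervals.
#' @param period fixed interval of the periodic process (s).
#' @return an object of class `point_process_model`.
#' @name point_process_model
#' @examples
#' gamma_renewal(shape = 2, rate = 2)     # mean ISI 1 s, FF -> 0.5
#' periodic_process(period = 203.39)
NULL

ppm <- function(family, ...) {
  structure(list(family = family, ...), class = "point_process_model")
}

#' @rdname point_process_model
#' @export
gamma_renewal <- function(shape, rate) {
  stopifnot(shape > 0, rate > 0)
  ppm("gamma_renewal", shape = shape, rate = rate)
}

#' @rdname point_process_model
#' @export
inverse_gaussian_renewal <- function(mean, shape_ig) {
  stopifnot(mean > 0, shape_ig > 0)
  ppm("inverse_gaussian_renewal", mean = mean, shape_ig = shape_ig)
}

#' @rdname point_process_model
#' @export
exponential_refractory <- function(rate, refractory) {
  stopifnot(rate > 0, refractory >= 0)
  ppm("exponential_refractory", rate = rate, refractory = refractory)
}

#' @rdname point_process_model
#' @export
markov_poisson <- function(p, rates) {
  stopifnot(p >= 0, p <= 1, length(rates) == 2L, all(rates > 0))
  ppm("markov_poisson", p = p, rates = as.numeric(rates))
}

#' @rdname point_process_model
#' @export
alternating_poisson <- function(p, factor) {
  stopifnot(p > 0, factor > 0)
  ppm("alternating_poisson", p = p, factor = factor)
}

#' @rdname point_process_model
#' @export
periodic_process <- function(period) {
  stopifnot(period > 0)
  ppm("periodic", period = period)
}

#' @export
print.point_process_model <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat(sprintf("point_process_model: %s(%s)\n", x$family,
              paste(names(pars), vapply(pars, function(p)
                paste(format(p, digits = 6), collapse = "/"), ""),
                sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Mean interspike interval implied by a point-process model
#'
#' @param model a [point_process_model].
#' @return mean ISI in seconds (for the rate-switching families, the
#'   equal-weight average of the per-state mean intervals).
#' @export
mean_isi <- function(model) {
  stopifnot(inherits(model, "point_process_model"))
  switch(model$family,
    gamma_renewal = model$shape / model$rate,
    inverse_gaussian_renewal = model$mean,
    exponential_refractory = model$refractory + 1 / model$rate,
    markov_poisson = mean(1 / model$rates),
    alternating_poisson = mean(1 / (model$p * c(1, model$factor))),
    periodic = model$period,
    stop("unknown model family", call. = FALSE))
}

# Inverse-Gaussian sampler (Michael-Schucany-Haas transformation).
rinvgauss <- function(n, mean, shape) {
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Draw interspike intervals from a point-process model
#'
#' For the renewal families the ISIs are i.i.d. draws from the named ISI
#' distribution. For `markov_poisson` a hidden two-state chain switches
#' with probability `p` after each interval and the current state's rate
#' generates an exponential ISI; for `alternating_poisson` the two rates
#' `p` and `p * factor` alternate deterministically. Both degenerate to a
#' homogeneous Poisson process when the two rates coincide.
#'
#' @param model a [point_process_model].
#' @param n number of intervals, `>= 1`.
#' @param seed optional integer seed; fixed seed gives identical output.
#' @return numeric vector of `n` positive intervals (s).
#' @export
generate_isis <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "point_process_model"), n >= 1)
  n <- as.integer(n)
  with_seed(seed, switch(model$family,
    gamma_renewal =
      stats::rgamma(n, shape = model$shape, rate = model$rate),
    inverse_gaussian_renewal =
      rinvgauss(n, mean = model$mean, shape = model$shape_ig),
    exponential_refractory =
      model$refractory + stats::rexp(n, rate = model$rate),
    markov_poisson = {
      # state path: switch after each interval with probability p
      switches <- stats::runif(n) < model$p
      state <- cumsum(c(sample(0:1, 1L), switches[-n])) %% 2L
      stats::rexp(n, rate = model$rates[state + 1L])
    },
    alternating_poisson = {
      rates <- model$p * c(1, model$factor)
      stats::rexp(n, rate = rates[(seq_len(n) %% 2L) + 1L])
    },
    periodic = rep(model$period, n),
    stop("unknown model family", call. = FALSE)))
}

#' Generate a spike train from ISI and amplitude models
#'
#' Spike times are the cumulative sums of model-drawn ISIs truncated at
#' `duration`; amplitudes are i.i.d. gamma draws in shape/scale form.
#'
#' @param model a [point_process_model] for the ISIs.
#' @param amplitude_shape,amplitude_scale gamma amplitude parameters
#'   (scale in mV); amplitude mean = `amplitude_shape * amplitude_scale`.
#' @param duration recording duration (s), > 0.
#' @param seed optional integer seed.
#' @return a [spike_train()] (possibly empty when the first ISI exceeds
#'   `duration`).
#' @export
generate_spike_train <- function(model, amplitude_shape, amplitude_scale,
                                 duration, seed = NULL) {
  stopifnot(inherits(model, "point_process_model"), duration > 0,
            amplitude_shape > 0, amplitude_scale > 0)
  with_seed(seed, {
    mu <- mean_isi(model)
    n_guess <- max(16L, ceiling(duration / mu * 1.5 + 10 * sqrt(duration / mu)))
    times <- cumsum(generate_isis(model, n_guess))
    while (times[length(times)] < duration) {
      times <- c(times, times[length(times)] +
                   cumsum(generate_isis(model, n_guess)))
    }
    times <- times[times <= duration]
    # events closer than floating-point resolution merge into one
    if (length(times) > 1L) times <- times[c(TRUE, diff(times) > 0)]
    amps <- if (length(times)) {
      stats::rgamma(length(times), shape = amplitude_shape,
                    scale = amplitude_scale)
    } else numeric(0)
    spike_train(times, amps, duration)
  })
}
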
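#' Empirical Fano-factor curve of a spike train
#'
#' Computes the Fano factor FF(w) = Var(N(w)) / E[N(w)] of window counts
#' on a log-spaced grid of window sizes, using non-overlapping windows
#' (see [fano_factor()]). Windows at which FF is undefined (zero mean
#' count) are flagged, not dropped.
#'
#' @param train a [spike_train()].
#' @param w_min,w_max window-size range in seconds;
#'   `w_max <= duration / 2`.
#' @param n_points number of log-spaced windows.
#' @return object of class `fano_curve`: a data.frame with columns
#'   `window` (s), `ff`, `n_windows`, `undefined`, plus attribute
#'   `model_label`.
#' @export
empirical_fano_curve <- function(train, w_min = 0.1, w_max = 100,
                                 n_points = 30L) {
  stopifnot(inherits(train, "spike_train"), w_min > 0, w_max > w_min,
            n_points >= 2L)
  if (w_max > train$duration / 2) {
    stop("w_max must not exceed half the recording duration",
         call. = FALSE)
  }
  windows <- exp(seq(log(w_min), log(w_max), length.out = n_points))
  ff <- vapply(windows, function(w) fano_factor(train, w), numeric(1))
  out <- data.frame(window = windows, ff = as.numeric(ff),
                    n_windows = floor(train$duration / windows),
                    undefined = is.na(ff))
  attr(out, "model_label") <- "empirical"
  class(out) <- c("fano_curve", class(out))
  out
}

#' Monte-Carlo Fano-factor curve of a point-process model
#'
#' Estimates FF(w) for a theoretical spike-train model by simulating
#' `n_reps` long realizations and averaging the empirical window-count
#' Fano factor at each window size. This Monte-Carlo estimator is the
#' authoritative implementation of the theoretical reference curves
#' (the closed-form renewal expression in the source material fails the
#' Poisson self-check FF = 1 as printed; see the methods vignette).
#'
#' @param model a [point_process_model].
#' @param windows window-size grid in seconds; default 30 log-spaced
#'   points covering 0.1 to 100 mean ISIs of the model.
#' @param n_reps number of independent realizations to average.
#' @param duration realization length in seconds; default covers the
#'   largest window at least 40 times.
#' @param seed optional integer seed.
#' @return a `fano_curve` data.frame (columns `window`, `ff`,
#'   `n_windows`, `undefined`) with `model_label` attribute.
#' @export
theoretical_fano_curve <- function(model, windows = NULL, n_reps = 10L,
                                   duration = NULL, seed = NULL) {
  stopifnot(inherits(model, "point_process_model"), n_reps >= 1)
  mu <- mean_isi(model)
  if (is.null(windows)) {
    windows <- exp(seq(log(0.1 * mu), log(100 * mu), length.out = 30L))
  }
  stopifnot(all(diff(windows) > 0), all(windows > 0))
  if (is.null(duration)) duration <- 40 * max(windows)
  if (duration < 2 * max(windows)) {
    stop("duration must cover the largest window at least twice",
         call. = FALSE)
  }
  with_seed(seed, {
    ff_mat <- vapply(seq_len(n_reps), function(rep) {
      n_guess <- ceiling(duration / mu * 1.5 + 100)
      times <- cumsum(generate_isis(model, n_guess))
      while (times[length(times)] < duration) {
        times <- c(times, times[length(times)] +
                     cumsum(generate_isis(model, n_guess)))
      }
      times <- times[times <= duration]
      if (length(times) > 1L) times <- times[c(TRUE, diff(times) > 0)]
      tr <- spike_train(times, rep(1, length(times)), duration)
      vapply(windows, function(w) fano_factor(tr, w), numeric(1))
    }, numeric(length(windows)))
    ff_mat <- matrix(ff_mat, nrow = length(windows))
    out <- data.frame(window = windows,
                      ff = rowMeans(ff_mat, na.rm = TRUE),
                      n_windows = floor(duration / windows) * n_reps,
                      undefined = apply(ff_mat, 1L, function(r)
                        all(is.na(r))))
    attr(out, "model_label") <- model$family
    class(out) <- c("fano_curve", class(out))
    out
  })
}

#' Large-window Fano-factor asymptote of a renewal process
#'
#' For a renewal process the Fano factor of window counts converges to
#' the squared coefficient of variation of the interspike-interval
#' distribution as the window grows. Closed forms: gamma `1/k`; inverse
#' Gaussian `mean/shape_ig`; exponential with refractory period
#' `(1/rate)^2 / (refractory + 1/rate)^2`; periodic 0.
#'
#' @param model a renewal-family [point_process_model].
#' @return the dimensionless large-window FF limit (ISI CV squared).
#'   Rate-switching families (`markov_poisson`, `alternating_poisson`)
#'   are not renewal processes in this sense and raise an error; use
#'   [theoretical_fano_curve()] for them.
#' @examples
#' ff_asymptote(gamma_renewal(shape = 2, rate = 1))          # 0.5
#' ff_asymptote(gamma_renewal(shape = 1 / 0.22^2, rate = 1)) # 0.0484
#' @export
ff_asymptote <- function(model) {
  stopifnot(inherits(model, "point_process_model"))
  switch(model$family,
    gamma_renewal = 1 / model$shape,
    inverse_gaussian_renewal = model$mean / model$shape_ig,
    exponential_refractory = {
      m_exp <- 1 / model$rate
      m_exp^2 / (model$refractory + m_exp)^2
    },
    periodic = 0,
    stop(sprintf(
      "no closed-form asymptote for family '%s'; use theoretical_fano_curve",
      model$family), call. = FALSE))
}
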
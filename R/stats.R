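#' Descriptive summary statistics block
#'
#' Computes the statistics block used throughout the amplitude and
#' interspike-interval analyses: mean, median, quartiles (linear
#' interpolation, inclusive method), min/max, sample SD (n-1 denominator),
#' peak-to-peak distance, RMS, and the plugin skewness/kurtosis.
#'
#' @param values numeric vector, at least one finite value.
#' @param units unit label carried through for reporting (e.g. `"mV"`,
#'   `"s"`).
#' @return an object of class `summary_stats`: a list with `n`, `mean`,
#'   `median`, `q1`, `q3`, `min`, `max`, `sd`, `peak_to_peak`, `rms`,
#'   `skewness`, `kurtosis`, `units`. For `n == 1` the dispersion fields
#'   are 0 (`sd`) or `NA` (moment ratios) and `degenerate = TRUE` is set.
#' @examples
#' s <- summarize(c(0.38, 2.86, 4.96, 6.69, 15.01), units = "mV")
#' s$peak_to_peak  # 14.63
#' @export
summarize <- function(values, units = "") {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  stop_if_not_finite(values, "values")
  n <- length(values)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  degenerate <- n < 2L || stats::var(values) == 0
  out <- list(
    n = n,
    mean = mean(values),
    median = q[2L],
    q1 = q[1L],
    q3 = q[3L],
    min = min(values),
    max = max(values),
    sd = if (n >= 2L) stats::sd(values) else 0,
    peak_to_peak = max(values) - min(values),
    rms = sqrt(mean(values^2)),
    skewness = if (degenerate) NA_real_ else skewness(values),
    kurtosis = if (degenerate) NA_real_ else kurtosis(values),
    units = units,
    degenerate = degenerate)
  class(out) <- "summary_stats"
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  u <- if (nzchar(x$units)) paste0(" [", x$units, "]") else ""
  cat(sprintf("summary_stats%s: n = %d\n", u, x$n))
  cat(sprintf("  mean %.5g, sd %.5g, median %.5g, q1 %.5g, q3 %.5g\n",
              x$mean, x$sd, x$median, x$q1, x$q3))
  cat(sprintf("  min %.5g, max %.5g, peak-to-peak %.5g, rms %.5g\n",
              x$min, x$max, x$peak_to_peak, x$rms))
  cat(sprintf("  skewness %.5g, kurtosis %.5g\n", x$skewness, x$kurtosis))
  invisible(x)
}

#' Plugin skewness
#'
#' Moment-ratio estimator `m3 / m2^(3/2)` with population (n-denominator)
#' central moments. Zero for symmetric samples; the convention under which
#' a gamma(k) distribution has skewness `2/sqrt(k)`.
#'
#' @param values numeric vector, `n >= 2`, nonzero variance.
#' @return dimensionless skewness.
#' @export
skewness <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need n >= 2", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("zero variance: skewness undefined", call. = FALSE)
  mean((values - m)^3) / m2^1.5
}

#' Plugin (non-excess) kurtosis
#'
#' Moment-ratio estimator `m4 / m2^2` with population central moments;
#' a normal distribution has kurtosis 3, and the estimator is bounded
#' below by 1 for any sample with `n >= 2`.
#'
#' @inheritParams skewness
#' @return dimensionless kurtosis (normal = 3).
#' @export
kurtosis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need n >= 2", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("zero variance: kurtosis undefined", call. = FALSE)
  mean((values - m)^4) / m2^2
}

#' Gamma probability density in shape/scale form
#'
#' Density of the gamma distribution with shape `shape` and scale `scale`,
#' mean `shape * scale`. The amplitude fits report a parameter pair
#' (a = 32.27402, b = 0.01904) whose product reproduces the sample mean
#' only when `b` is read as a scale, so scale is the stored convention
#' throughout this package (see the methods vignette).
#'
#' @param x positive evaluation points.
#' @param shape shape parameter, > 0.
#' @param scale scale parameter, > 0 (data units).
#' @return density values, units 1/`scale`-unit.
#' @export
gamma_pdf <- function(x, shape, scale) {
  stopifnot(shape > 0, scale > 0)
  if (any(x <= 0)) stop("gamma density requires x > 0", call. = FALSE)
  stats::dgamma(x, shape = shape, scale = scale)
}

#' Maximum-likelihood gamma fit
#'
#' Fits a gamma distribution in shape/scale form by profile maximum
#' likelihood: Newton iteration on
#' `log(alpha) - digamma(alpha) = log(mean(x)) - mean(log(x))`,
#' started from the method-of-moments estimate, with
#' `scale = mean(x) / alpha_hat` (so the implied mean equals the sample
#' mean exactly).
#'
#' @param values positive sample, `n >= 10`.
#' @param tol relative convergence tolerance on the shape update.
#' @param max_iter maximum Newton iterations.
#' @return object of class `gamma_fit`: list with `shape`, `scale`,
#'   `log_likelihood` (nats), `n`, `converged`, `iterations`.
#' @examples
#' set.seed(1)
#' fit_gamma_mle(rgamma(1000, shape = 4, scale = 2))
#' @export
fit_gamma_mle <- function(values, tol = 1e-10, max_iter = 100L) {
  values <- as.numeric(values)
  if (length(values) < 10L) stop("need n >= 10 for a gamma fit",
                                 call. = FALSE)
  if (any(values <= 0)) stop("gamma fit requires positive data",
                             call. = FALSE)
  m <- mean(values)
  s <- log(m) - mean(log(values))  # always >= 0, = 0 only for constant data
  if (s <= 0) stop("degenerate sample: all values equal", call. = FALSE)
  alpha <- m^2 / stats::var(values)  # method-of-moments start
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    f <- log(alpha) - digamma(alpha) - s
    fp <- 1 / alpha - trigamma(alpha)
    step <- f / fp
    alpha_new <- alpha - step
    if (alpha_new <= 0) alpha_new <- alpha / 2  # keep iterate positive
    if (abs(alpha_new - alpha) / alpha < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  scale <- m / alpha
  ll <- sum(stats::dgamma(values, shape = alpha, scale = scale, log = TRUE))
  structure(list(shape = alpha, scale = scale, log_likelihood = ll,
                 n = length(values), converged = converged,
                 iterations = iter),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf(
    "gamma_fit: shape %.6g, scale %.6g (implied mean %.6g), n = %d\n",
    x$shape, x$scale, x$shape * x$scale, x$n))
  cat(sprintf("  log-likelihood %.6g, converged: %s (%d iterations)\n",
              x$log_likelihood, x$converged, x$iterations))
  invisible(x)
}

#' Scott bandwidth for kernel density estimation
#'
#' `h = n^(-1/5) * 1.06 * min(sd, IQR / 1.34)`.
#'
#' @param values numeric sample, `n >= 2`, not all equal.
#' @return bandwidth in data units.
#' @export
scott_bandwidth <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need n >= 2", call. = FALSE)
  s <- stats::sd(values)
  iqr <- stats::IQR(values, type = 7)
  if (s == 0 && iqr == 0) {
    stop("degenerate sample: zero spread", call. = FALSE)
  }
  cand <- c(s, iqr / 1.34)
  spread <- min(cand[cand > 0])
  n^(-1 / 5) * 1.06 * spread
}

#' Gaussian kernel density estimate
#'
#' Evaluates the Gaussian-kernel density estimate
#' `f(x) = (1/(n h)) * sum_i K((x - x_i)/h)` on a supplied grid.
#'
#' @param values numeric sample.
#' @param bandwidth kernel bandwidth `h > 0`; default [scott_bandwidth()].
#' @param grid ordered evaluation points; default 512 points spanning the
#'   data plus/minus 4 bandwidths.
#' @return object of class `kde_estimate`: list with `grid`, `density`,
#'   `bandwidth`, `n`. The trapezoid integral of `density` over the default
#'   grid is 1 to within 1%.
#' @export
kde <- function(values, bandwidth = scott_bandwidth(values), grid = NULL) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty sample", call. = FALSE)
  stopifnot(bandwidth > 0)
  if (is.null(grid)) {
    grid <- seq(min(values) - 4 * bandwidth, max(values) + 4 * bandwidth,
                length.out = 512L)
  }
  if (!length(grid)) stop("empty grid", call. = FALSE)
  if (is.unsorted(grid, strictly = FALSE)) stop("grid must be ordered",
                                                call. = FALSE)
  dens <- vapply(grid, function(x0) {
    mean(stats::dnorm((x0 - values) / bandwidth)) / bandwidth
  }, numeric(1))
  structure(list(grid = grid, density = dens, bandwidth = bandwidth,
                 n = length(values)),
            class = "kde_estimate")
}

#' Fano factor of spike counts in fixed windows
#'
#' The recording `[0, duration)` is tiled with consecutive non-overlapping
#' windows of length `window` (a final partial window is discarded), spikes
#' are counted per window, and `FF = Var(N) / E[N]` is returned with the
#' sample (n-1) variance. FF = 1 for a Poisson process; FF < 1 indicates
#' sub-Poisson (regular) spiking.
#'
#' @param train a [spike_train()].
#' @param window window length in seconds; `duration >= 2 * window`.
#' @return dimensionless Fano factor; `NA` (with attribute
#'   `undefined = TRUE`) when the mean count is zero.
#' @export
fano_factor <- function(train, window) {
  stopifnot(inherits(train, "spike_train"), window > 0)
  n_win <- floor(train$duration / window)
  if (n_win < 2L) stop("need at least 2 complete windows", call. = FALSE)
  idx <- floor(train$spike_times / window)
  idx <- idx[idx < n_win]
  counts <- tabulate(idx + 1L, nbins = n_win)
  m <- mean(counts)
  if (m == 0) return(structure(NA_real_, undefined = TRUE))
  stats::var(counts) / m
}
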
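#' Construct a uniformly sampled voltage trace
#'
#' A `voltage_trace` holds a potential time series sampled at a fixed rate,
#' stored internally in millivolts, together with condition metadata
#' (label, CS concentration in mg/ml, optional temperature).
#'
#' @param times numeric vector of sample times in seconds, strictly
#'   increasing with a uniform step.
#' @param values numeric vector of potentials, same length as `times`.
#' @param units unit of `values`: `"mV"` (stored as-is) or `"V"`
#'   (converted to mV on construction).
#' @param condition condition label, e.g. `"1.86"` or `"water"`.
#' @param cs_mg_ml CS concentration in mg/ml (`NA` for water control).
#' @param temperature_C optional temperature in degrees Celsius.
#' @return an object of class `voltage_trace` with elements `times` (s),
#'   `values` (mV), `sampling_rate` (Hz), `condition`, `cs_mg_ml`,
#'   `temperature_C`.
#' @examples
#' tr <- voltage_trace(0:9, sin(0:9), units = "mV")
#' tr$sampling_rate
#' @export
voltage_trace <- function(times, values, units = c("mV", "V"),
                          condition = NA_character_, cs_mg_ml = NA_real_,
                          temperature_C = NA_real_) {
  units <- match.arg(units)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("a voltage trace needs at least 2 samples", call. = FALSE)
  }
  stop_if_not_finite(times, "times")
  stop_if_not_finite(values, "values")
  steps <- diff(times)
  if (any(steps <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  step <- stats::median(steps)
  if (any(abs(steps - step) > 1e-9 * max(step, 1))) {
    stop("non-uniform sampling: time steps differ beyond tolerance",
         call. = FALSE)
  }
  if (units == "V") values <- values * 1000
  structure(
    list(times = times, values = values, sampling_rate = 1 / step,
         condition = condition, cs_mg_ml = cs_mg_ml,
         temperature_C = temperature_C),
    class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf(
    "voltage_trace: %d samples at %.6g Hz (%.6g s), condition %s\n",
    length(x$values), x$sampling_rate,
    x$times[length(x$times)] - x$times[1L],
    if (is.na(x$condition)) "<unset>" else x$condition))
  cat(sprintf("  potential [mV]: mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
              mean(x$values), stats::sd(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read a voltage trace from CSV
#'
#' Expects two numeric columns, time in seconds then potential; one header
#' line is permitted. The potential unit is taken from the header when it
#' reads `potential_mV` / `potential_V`, otherwise from `units`.
#'
#' @param path path to a CSV/TSV file.
#' @param units fallback potential unit when the header does not declare one.
#' @param ... further metadata passed to [voltage_trace()] (`condition`,
#'   `cs_mg_ml`, `temperature_C`).
#' @return a [voltage_trace()].
#' @export
read_trace <- function(path, units = c("mV", "V"), ...) {
  units <- match.arg(units)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- grepl("[A-Za-z]", first)
  if (has_header) {
    hdr <- strsplit(first, sep, fixed = TRUE)[[1L]]
    if (any(grepl("potential_V$", hdr))) units <- "V"
    if (any(grepl("potential_mV$", hdr))) units <- "mV"
  }
  df <- utils::read.table(path, header = has_header, sep = sep,
                          colClasses = "numeric")
  if (ncol(df) < 2L) stop("expected two columns (time, potential)",
                          call. = FALSE)
  voltage_trace(df[[1L]], df[[2L]], units = units, ...)
}

#' Write a voltage trace to CSV
#'
#' Writes header `time_s,potential_mV` so that the unit travels with the
#' file; [read_trace()] round-trips the values losslessly.
#'
#' @param trace a [voltage_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "voltage_trace"))
  df <- data.frame(time_s = trace$times, potential_mV = trace$values)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a spike train
#'
#' Ordered spike times with per-spike amplitudes over a known recording
#' duration.
#'
#' @param spike_times numeric vector of spike times in seconds, strictly
#'   increasing, within `[0, duration]`.
#' @param amplitudes positive spike amplitudes in mV, same length.
#' @param duration recording duration in seconds.
#' @return an object of class `spike_train`.
#' @examples
#' spike_train(c(10, 20, 35), c(0.5, 0.7, 0.6), duration = 50)
#' @export
spike_train <- function(spike_times, amplitudes, duration) {
  spike_times <- as.numeric(spike_times)
  amplitudes <- as.numeric(amplitudes)
  duration <- as.numeric(duration)
  if (length(spike_times) != length(amplitudes)) {
    stop("spike_times and amplitudes must have equal length", call. = FALSE)
  }
  stopifnot(length(duration) == 1L, is.finite(duration), duration > 0)
  if (length(spike_times)) {
    stop_if_not_finite(spike_times, "spike_times")
    stop_if_not_finite(amplitudes, "amplitudes")
    if (any(diff(spike_times) <= 0)) {
      stop("spike_times must be strictly increasing", call. = FALSE)
    }
    if (spike_times[1L] < 0 || spike_times[length(spike_times)] > duration) {
      stop("spike_times must lie within [0, duration]", call. = FALSE)
    }
    if (any(amplitudes <= 0)) {
      stop("amplitudes must be positive", call. = FALSE)
    }
  }
  structure(list(spike_times = spike_times, amplitudes = amplitudes,
                 duration = duration),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  n <- length(x$spike_times)
  cat(sprintf("spike_train: %d spikes over %.6g s (rate %.6g spikes/s)\n",
              n, x$duration, n / x$duration))
  if (n > 0) {
    cat(sprintf("  amplitudes [mV]: mean %.4g, range [%.4g, %.4g]\n",
                mean(x$amplitudes), min(x$amplitudes), max(x$amplitudes)))
  }
  invisible(x)
}

#' Interspike intervals of a spike train
#'
#' @param train a [spike_train()] with at least 2 spikes.
#' @return numeric vector of first differences of the spike times (s),
#'   of length `n - 1`.
#' @examples
#' interspike_intervals(spike_train(c(10, 20, 35), c(1, 1, 1), 50))
#' @export
interspike_intervals <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (length(train$spike_times) < 2L) {
    stop("need at least 2 spikes to form interspike intervals",
         call. = FALSE)
  }
  diff(train$spike_times)
}

#' Mean firing rate of a spike train
#'
#' @param train a [spike_train()].
#' @return spikes per second, `n_spikes / duration`.
#' @export
firing_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (train$duration <= 0) stop("duration must be positive", call. = FALSE)
  length(train$spike_times) / train$duration
}
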
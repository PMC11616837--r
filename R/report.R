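#' Full statistical analysis of a spike train
#'
#' Assembles the per-condition analysis block: descriptive statistics of
#' amplitudes and interspike intervals, the maximum-likelihood gamma
#' amplitude fit, firing rate, ISI coefficient of variation, and the
#' Fano factor at a configured window.
#'
#' @param train a [spike_train()].
#' @param condition condition label carried into the report.
#' @param fano_window window for the Fano factor, s.
#' @param fit_amplitudes fit the gamma amplitude model (needs >= 10
#'   spikes).
#' @return object of class `analysis_report`: list with `condition`,
#'   `n_spikes`, `duration_s`, `amplitude_stats`, `isi_stats`
#'   ([summarize()] blocks or `NULL` when too few spikes), `gamma_fit`
#'   (or `NULL`), `firing_rate` (spikes/s), `cv_isi`, `fano`,
#'   `fano_window_s`.
#' @export
analyze_spike_train <- function(train, condition = NA_character_,
                                fano_window = 1000,
                                fit_amplitudes = TRUE) {
  stopifnot(inherits(train, "spike_train"))
  n <- length(train$spike_times)
  amp_stats <- if (n >= 1L) summarize(train$amplitudes, units = "mV")
  isis <- if (n >= 2L) interspike_intervals(train)
  isi_stats <- if (!is.null(isis)) summarize(isis, units = "s")
  fit <- if (fit_amplitudes && n >= 10L) fit_gamma_mle(train$amplitudes)
  cv <- if (!is.null(isis) && mean(isis) > 0) {
    stats::sd(isis) / mean(isis)
  } else NA_real_
  ff <- if (train$duration >= 2 * fano_window) {
    as.numeric(fano_factor(train, fano_window))
  } else NA_real_
  structure(list(condition = condition, n_spikes = n,
                 duration_s = train$duration,
                 amplitude_stats = amp_stats, isi_stats = isi_stats,
                 gamma_fit = fit,
                 firing_rate = firing_rate(train), cv_isi = cv,
                 fano = ff, fano_window_s = fano_window),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis_report (condition %s): %d spikes over %.6g s\n",
              x$condition, x$n_spikes, x$duration_s))
  cat(sprintf("  firing rate %.6g spikes/s, CV(ISI) %.4g, FF(%g s) %.4g\n",
              x$firing_rate, x$cv_isi, x$fano_window_s, x$fano))
  if (!is.null(x$amplitude_stats)) {
    cat("  amplitudes: "); utils::str(x$amplitude_stats[
      c("mean", "sd", "min", "max")], give.head = FALSE)
  }
  if (!is.null(x$gamma_fit)) {
    cat(sprintf("  gamma fit: shape %.5f, scale %.5f\n",
                x$gamma_fit$shape, x$gamma_fit$scale))
  }
  invisible(x)
}

stats_to_list <- function(s) {
  if (is.null(s)) return(NULL)
  s[c("n", "mean", "median", "q1", "q3", "min", "max", "sd",
      "peak_to_peak", "rms", "skewness", "kurtosis", "units")]
}

#' Write an analysis report to JSON
#'
#' Serializes every field of an [analyze_spike_train()] report,
#' unit-annotated, to a machine-readable JSON file. Reports containing
#' non-finite statistics (other than the `NA` placeholders of an empty
#' train) are rejected.
#'
#' @param report an `analysis_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  check_block <- function(s) {
    if (is.null(s)) return(invisible())
    vals <- unlist(s[c("mean", "median", "q1", "q3", "min", "max", "sd",
                       "peak_to_peak", "rms")])
    if (any(is.nan(vals)) || any(is.infinite(vals))) {
      stop("report contains non-finite statistics", call. = FALSE)
    }
  }
  check_block(report$amplitude_stats)
  check_block(report$isi_stats)
  payload <- list(
    condition = report$condition,
    n_spikes = report$n_spikes,
    duration_s = report$duration_s,
    amplitude_stats = stats_to_list(report$amplitude_stats),
    isi_stats = stats_to_list(report$isi_stats),
    gamma_fit = if (!is.null(report$gamma_fit)) {
      report$gamma_fit[c("shape", "scale", "log_likelihood", "n",
                         "converged")]
    },
    firing_rate_spikes_per_s = report$firing_rate,
    cv_isi = report$cv_isi,
    fano = report$fano,
    fano_window_s = report$fano_window_s)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an analysis report written by [write_report()]
#'
#' @param path JSON path.
#' @return the report as a list (same field layout as
#'   [analyze_spike_train()]).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Serialize a spike train to JSON
#'
#' @param train a [spike_train()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spike_train <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  jsonlite::write_json(
    list(spike_times_s = train$spike_times,
         amplitudes_mV = train$amplitudes,
         duration_s = train$duration),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spike train written by [write_spike_train()]
#'
#' @param path JSON path.
#' @return a [spike_train()].
#' @export
read_spike_train <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spike_train(x$spike_times_s, x$amplitudes_mV, x$duration_s)
}
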
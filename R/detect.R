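#' Spike detection configuration
#'
#' @param baseline_window length of the centered rolling-median baseline
#'   window, in seconds.
#' @param threshold_k detection threshold in multiples of the robust noise
#'   scale (1.4826 x MAD of the baseline-subtracted trace).
#' @param min_amplitude absolute floor on the detection threshold, mV.
#' @param refractory minimum separation between accepted spikes, s.
#' @return object of class `detection_config`.
#' @details Defaults (600 s window, k = 5, 0.3 mV floor, 60 s refractory)
#'   sit below the smallest published spike amplitude (0.38 mV) while
#'   staying well above sensor noise, and the refractory period is short
#'   against the ~200 s interspike intervals of the recordings.
#' @export
detection_config <- function(baseline_window = 600, threshold_k = 5,
                             min_amplitude = 0.3, refractory = 60) {
  stopifnot(baseline_window > 0, threshold_k > 0, min_amplitude > 0,
            refractory > 0)
  structure(list(baseline_window = baseline_window,
                 threshold_k = threshold_k,
                 min_amplitude = min_amplitude,
                 refractory = refractory),
            class = "detection_config")
}

#' Detect spikes in a voltage trace
#'
#' Robust threshold detector: the baseline is a centered rolling median
#' over `baseline_window`; the noise scale is 1.4826 x the median absolute
#' deviation of the baseline-subtracted trace; spikes are local maxima of
#' the residual exceeding `max(threshold_k * noise_scale, min_amplitude)`
#' and separated by at least `refractory` seconds. When two candidates
#' fall within one refractory period the larger amplitude is kept
#' (deterministic tie-break). Amplitude is the residual at the peak
#' (peak minus baseline).
#'
#' @param trace a [voltage_trace()].
#' @param config a [detection_config()].
#' @return a [spike_train()] (times in seconds from trace start,
#'   amplitudes in mV, duration = trace span plus one sample).
#' @examples
#' rec <- generate_voltage_trace("1.86", duration = 7200, seed = 1)
#' detect_spikes(rec$trace)
#' @export
detect_spikes <- function(trace, config = detection_config()) {
  stopifnot(inherits(trace, "voltage_trace"),
            inherits(config, "detection_config"))
  v <- trace$values
  n <- length(v)
  rate <- trace$sampling_rate
  k <- floor(config$baseline_window * rate)
  if (n < k) stop("trace shorter than the baseline window", call. = FALSE)
  if (k %% 2 == 0) k <- k + 1  # runmed needs an odd width
  k <- max(k, 3L)
  baseline <- stats::runmed(v, k, endrule = "median")
  resid <- v - baseline
  noise <- stats::mad(resid)  # 1.4826 * MAD
  threshold <- max(config$threshold_k * noise, config$min_amplitude)
  # local maxima of the residual above threshold
  cand <- which(resid > threshold)
  cand <- cand[resid[cand] >= c(-Inf, resid)[cand] &
               resid[cand] >= c(resid, -Inf)[cand + 1L]]
  t0 <- trace$times[1L]
  duration <- (trace$times[n] - t0) + 1 / rate
  if (!length(cand)) {
    return(spike_train(numeric(0), numeric(0), duration))
  }
  # refractory enforcement: accept in decreasing amplitude order
  ord <- cand[order(resid[cand], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in ord) {
    t_i <- trace$times[i]
    if (!length(accepted) ||
        all(abs(trace$times[accepted] - t_i) >= config$refractory)) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- sort(accepted)
  spike_train(trace$times[accepted] - t0, resid[accepted], duration)
}
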
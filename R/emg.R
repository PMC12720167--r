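# Trial-level EMG preprocessing: peak-to-peak MEP extraction and
# pre-activation rejection, plus a synthetic trace generator for testing.

#' EMG trace container
#'
#' A single-trial EMG recording with the sample index of the TMS pulse.
#'
#' @param samples voltage series in microvolts.
#' @param sampling_rate sampling rate in Hz (> 0); default 5000.
#' @param stimulus_index sample index of the TMS pulse (1-based, within the
#'   series).
#' @return Object of class `emg_trace`.
#' @export
emg_trace <- function(samples, sampling_rate = 5000, stimulus_index) {
  samples <- as.numeric(samples)
  check_scalar_number(sampling_rate, "sampling_rate")
  if (sampling_rate <= 0) stop_invalid("sampling_rate must be positive")
  stimulus_index <- as.integer(stimulus_index)
  if (stimulus_index < 1L || stimulus_index > length(samples)) {
    stop_invalid("stimulus_index outside the trace")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 stimulus_index = stimulus_index),
            class = "emg_trace")
}

ms_to_samples <- function(ms, rate) {
  as.integer(round(ms / 1000 * rate))
}

#' Peak-to-peak MEP amplitude in a post-stimulus window
#'
#' Maximum minus minimum voltage in the inclusive window
#' `[stimulus + window_start, stimulus + window_end]`. Window bounds in ms
#' are converted to sample indices by rounding to the nearest sample.
#' Invariant to DC offset by construction.
#'
#' @param trace an [emg_trace()].
#' @param window_start,window_end window bounds in ms after the pulse;
#'   defaults 18 and 35.
#' @return Amplitude in microvolts.
#' @export
peak_to_peak_amplitude <- function(trace, window_start = 18,
                                   window_end = 35) {
  if (window_start >= window_end) {
    stop_invalid("window_start must be before window_end")
  }
  i1 <- trace$stimulus_index + ms_to_samples(window_start,
                                             trace$sampling_rate)
  i2 <- trace$stimulus_index + ms_to_samples(window_end,
                                             trace$sampling_rate)
  if (i1 < 1L || i2 > length(trace$samples)) {
    stop_invalid("extraction window extends outside the trace")
  }
  seg <- trace$samples[i1:i2]
  max(seg) - min(seg)
}

#' Pre-stimulus muscle activity check
#'
#' A trial is rejected when the pre-stimulus peak-to-peak amplitude over
#' `[stimulus - pre_window, stimulus)` strictly exceeds the threshold
#' (exactly at threshold keeps the trial).
#'
#' @param trace an [emg_trace()].
#' @param threshold rejection threshold in microvolts; default 50.
#' @param pre_window pre-stimulus window length in ms; default 100.
#' @return `TRUE` when the trial is rejected for pre-activation, `FALSE`
#'   when it is kept.
#' @export
preactivation_check <- function(trace, threshold = 50, pre_window = 100) {
  npre <- ms_to_samples(pre_window, trace$sampling_rate)
  i1 <- trace$stimulus_index - npre
  if (i1 < 1L) {
    stop_invalid("trace holds less than ", pre_window,
                 " ms of pre-stimulus data")
  }
  seg <- trace$samples[i1:(trace$stimulus_index - 1L)]
  (max(seg) - min(seg)) > threshold
}

#' Synthetic EMG trace with one biphasic deflection
#'
#' Baseline noise plus a biphasic +A/2, -A/2 deflection of the requested
#' peak-to-peak amplitude at `stimulus + latency`. With zero noise and a
#' latency inside the extraction window, [peak_to_peak_amplitude()] returns
#' `mep_amplitude` exactly.
#'
#' @param mep_amplitude peak-to-peak deflection amplitude in microvolts.
#' @param latency deflection latency in ms after the pulse (>= 0); default
#'   25.
#' @param pre_noise_p2p approximate peak-to-peak amplitude of uniform
#'   baseline noise in microvolts; default 0.
#' @param sampling_rate Hz; default 5000.
#' @param seed integer seed; identical seeds give identical traces.
#' @param pre_ms,post_ms trace extent around the pulse in ms.
#' @return An [emg_trace()].
#' @export
synth_emg_trace <- function(mep_amplitude, latency = 25, pre_noise_p2p = 0,
                            sampling_rate = 5000, seed = NULL,
                            pre_ms = 150, post_ms = 80) {
  if (latency < 0) stop_invalid("latency must be non-negative")
  npre <- ms_to_samples(pre_ms, sampling_rate)
  npost <- ms_to_samples(post_ms, sampling_rate)
  n <- npre + npost + 1L
  samples <- if (pre_noise_p2p > 0) {
    with_seed(seed, stats::runif(n, -pre_noise_p2p / 2, pre_noise_p2p / 2))
  } else {
    rep(0, n)
  }
  stim <- npre + 1L
  i <- stim + ms_to_samples(latency, sampling_rate)
  if (i <= n) samples[i] <- samples[i] + mep_amplitude / 2
  if (i + 1L <= n) samples[i + 1L] <- samples[i + 1L] - mep_amplitude / 2
  emg_trace(samples, sampling_rate, stim)
}

#' Batch MEP extraction with rejection bookkeeping
#'
#' Applies window extraction and the pre-activation rule to a list of
#' traces.
#'
#' @param traces list of [emg_trace()] objects.
#' @param window_start,window_end extraction window in ms.
#' @param threshold,pre_window pre-activation rule parameters.
#' @return Data frame with `trial_id`, `p2p_uv`,
#'   `rejected_preactivation`.
#' @export
extract_mep_batch <- function(traces, window_start = 18, window_end = 35,
                              threshold = 50, pre_window = 100) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(trial_id = i,
               p2p_uv = peak_to_peak_amplitude(tr, window_start, window_end),
               rejected_preactivation =
                 preactivation_check(tr, threshold, pre_window))
  })
  do.call(rbind, rows)
}
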
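#' Peripheral conduction time
#'
#' Conduction time of the peripheral segment of the motor pathway, derived
#' from median-nerve stimulation responses recorded at the target muscle:
#' `(F-wave latency + M-wave latency - 1) / 2` in milliseconds. The F-wave
#' is the late response produced by antidromic motoneuron activation, the
#' M-wave the direct muscle response.
#'
#' @param f_wave_latency,m_wave_latency latencies in ms, strictly positive.
#' @return Peripheral conduction time in ms (vectorized).
#' @examples
#' peripheral_conduction_time(28, 3)  # 15 ms
#' @export
peripheral_conduction_time <- function(f_wave_latency, m_wave_latency) {
  if (any(!is.finite(f_wave_latency)) || any(!is.finite(m_wave_latency)) ||
      any(f_wave_latency <= 0) || any(m_wave_latency <= 0)) {
    stop("F-wave and M-wave latencies must be strictly positive", call. = FALSE)
  }
  (f_wave_latency + m_wave_latency - 1) / 2
}

#' Central motor conduction time (CMCT)
#'
#' CMCT estimates the conduction time of corticospinal fibres between the
#' motor cortex and the spinal alpha-motoneurons: the MEP onset latency
#' minus the peripheral conduction time. A prolonged CMCT indicates
#' demyelination or conduction block of central motor pathways; a decrease
#' is an improvement.
#'
#' A non-positive CMCT is physiologically impossible and indicates an
#' inconsistent latency set; such values are returned as-is but flagged via
#' the `"degenerate"` attribute so that the visual-analysis stage still
#' sees them and reports can mark them.
#'
#' @param mep_latency MEP onset latency in ms.
#' @inheritParams peripheral_conduction_time
#' @return CMCT in ms (vectorized), with logical attribute `"degenerate"`
#'   marking entries `<= 0`.
#' @examples
#' central_motor_conduction_time(25, 28, 3)  # 10 ms
#' @export
central_motor_conduction_time <- function(mep_latency, f_wave_latency,
                                          m_wave_latency) {
  if (any(!is.finite(mep_latency)) || any(mep_latency <= 0)) {
    stop("MEP latency must be strictly positive", call. = FALSE)
  }
  pct <- peripheral_conduction_time(f_wave_latency, m_wave_latency)
  cmct <- mep_latency - pct
  structure(cmct, degenerate = cmct <= 0)
}

#' Construct a MEP trace
#'
#' A single surface-EMG sweep around one TMS pulse. Samples are in mV; the
#' stimulus onset index marks the sample at which the pulse was delivered,
#' and everything before it is the pre-stimulus window used to estimate the
#' noise floor.
#'
#' @param samples numeric vector of EMG samples (mV).
#' @param sampling_rate sampling rate in Hz (default 24 kHz).
#' @param stimulus_onset_index 1-based index of the stimulus sample.
#' @return Object of class `mep_trace`.
#' @export
mep_trace <- function(samples, sampling_rate = 24000,
                      stimulus_onset_index) {
  stopifnot(is.numeric(samples), length(samples) > 0,
            is.numeric(sampling_rate), sampling_rate > 0)
  stimulus_onset_index <- as.integer(stimulus_onset_index)
  if (stimulus_onset_index < 1L || stimulus_onset_index > length(samples)) {
    stop("stimulus_onset_index outside the sample range", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 stimulus_onset_index = stimulus_onset_index),
            class = "mep_trace")
}

# post-stimulus time (ms) -> sample index, clamped check left to callers
.trace_index <- function(trace, t_ms) {
  trace$stimulus_onset_index + round(t_ms * trace$sampling_rate / 1000)
}

#' Peak-to-peak MEP amplitude
#'
#' The difference in voltage between the maximal positive and maximal
#' negative deflection within a post-stimulus search window. The default
#' window of 15-60 ms excludes the stimulus artifact; it is configurable
#' because no standard window fits every muscle and latency range.
#'
#' @param trace an [mep_trace()].
#' @param window numeric length-2: start and end of the search window in ms
#'   after the stimulus.
#' @return Amplitude in mV (non-negative).
#' @export
peak_to_peak_amplitude <- function(trace, window = c(15, 60)) {
  stopifnot(inherits(trace, "mep_trace"), length(window) == 2L)
  if (window[2] <= window[1]) stop("empty amplitude window", call. = FALSE)
  i0 <- max(.trace_index(trace, window[1]), 1L)
  i1 <- min(.trace_index(trace, window[2]), length(trace$samples))
  if (i0 > i1) stop("amplitude window lies outside the trace", call. = FALSE)
  seg <- trace$samples[i0:i1]
  max(seg) - min(seg)
}

#' Detect MEP onset latency
#'
#' Automated replacement for visual onset scoring: the onset is the first
#' post-stimulus sample at which the rectified signal exceeds the
#' pre-stimulus noise threshold (pre-stimulus rectified mean plus `k_sd`
#' standard deviations) and stays above it for at least `min_duration` ms.
#' The detector backtracks from the sustained crossing to the first sample
#' of that supra-threshold run, so brief noise dips just after the true
#' onset do not bias the latency late.
#'
#' @inheritParams peak_to_peak_amplitude
#' @param k_sd threshold in pre-stimulus standard deviations (default 3).
#' @param min_duration minimum supra-threshold duration in ms (default 0.5).
#' @return Onset latency in ms after the stimulus, or `NA` when no
#'   sustained crossing exists (no detectable response).
#' @export
detect_mep_onset <- function(trace, k_sd = 3, min_duration = 0.5) {
  stopifnot(inherits(trace, "mep_trace"))
  pre <- trace$samples[seq_len(trace$stimulus_onset_index - 1L)]
  if (length(pre) < 10L) {
    stop("pre-stimulus window too short (needs >= 10 samples)", call. = FALSE)
  }
  rect <- abs(trace$samples)
  thr <- mean(abs(pre)) + k_sd * sd(abs(pre))
  post <- seq(trace$stimulus_onset_index, length(trace$samples))
  above <- rect[post] > thr
  need <- max(1L, ceiling(min_duration * trace$sampling_rate / 1000))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (length(hit) == 0) return(NA_real_)
  onset_idx <- post[starts[hit[1]]]
  (onset_idx - trace$stimulus_onset_index) / trace$sampling_rate * 1000
}

#' Summarize a bout of suprathreshold stimuli
#'
#' A TMS assessment bout applies a fixed number of suprathreshold pulses
#' (30 in the reference protocol); amplitude and latency are computed per
#' trace and then averaged into a single value per session. Traces whose
#' onset the detector cannot find contribute to the amplitude mean but are
#' excluded from the latency mean; the full bout size is kept in the
#' accounting.
#'
#' @param traces list of [mep_trace()] objects.
#' @param window amplitude search window (ms post-stimulus).
#' @param k_sd,min_duration onset-detector settings, see
#'   [detect_mep_onset()].
#' @return List with `mean_amplitude` (mV), `mean_latency` (ms, `NA` when
#'   no onset was detected in any trace), `n_used` (bout size) and
#'   `n_latency` (traces with a detected onset).
#' @export
summarize_mep_bout <- function(traces, window = c(15, 60), k_sd = 3,
                               min_duration = 0.5) {
  stopifnot(is.list(traces), length(traces) >= 1)
  amps <- vapply(traces, peak_to_peak_amplitude, numeric(1), window = window)
  lats <- vapply(traces, detect_mep_onset, numeric(1), k_sd = k_sd,
                 min_duration = min_duration)
  det <- !is.na(lats)
  list(mean_amplitude = mean(amps),
       mean_latency = if (any(det)) mean(lats[det]) else NA_real_,
       n_used = length(traces),
       n_latency = sum(det))
}

#' Suprathreshold stimulation intensity
#'
#' The bout intensity used to elicit MEPs: 120% of the resting motor
#' threshold, rounded to the nearest integer percent of maximum stimulator
#' output and capped at the hardware maximum of 100%MSO.
#'
#' @param rmt resting motor threshold in %MSO, in (0, 100].
#' @return Integer %MSO with logical attribute `"capped"`.
#' @examples
#' suprathreshold_intensity(64)  # 77 %MSO
#' @export
suprathreshold_intensity <- function(rmt) {
  if (any(!is.finite(rmt)) || any(rmt <= 0) || any(rmt > 100)) {
    stop("resting motor threshold must lie in (0, 100] %MSO", call. = FALSE)
  }
  raw <- round(1.2 * rmt)
  structure(pmin(raw, 100), capped = raw > 100)
}

#' Age-predicted maximum heart rate
#'
#' The standard 220 - age estimate (beats per minute), used to keep
#' exercise intensity below the aerobic threshold.
#'
#' @param age age in years, in (0, 120).
#' @return Predicted maximum heart rate in bpm (vectorized).
#' @export
hr_max <- function(age) {
  if (any(!is.finite(age)) || any(age <= 0) || any(age >= 120)) {
    stop("age must lie in (0, 120) years", call. = FALSE)
  }
  220 - age
}
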
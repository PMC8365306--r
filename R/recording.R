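#' Multi-channel stimulation pulse-train recording
#'
#' Sampled voltages around trains of biphasic, bipolar, current-controlled
#' stimulation pulses: `samples` holds channels x time in volts at
#' `sampling_rate` Hz, with known pulse onset sample indices.
#'
#' @param samples channels x time numeric matrix (volts); rownames are
#'   channel labels.
#' @param sampling_rate sampling rate (Hz, default 12207).
#' @param pulse_onsets strictly increasing onset sample indices; every onset
#'   must leave >= 50 ms of pre-stimulus samples and the full biphasic pulse
#'   within the record.
#' @param stim_amplitude_mA stimulation amplitude I0 (mA).
#' @param phase_width_ms phase width (default 1.2 ms).
#' @param stim_pair cathode/anode labels, e.g. `c("B4", "B3")`.
#' @return an object of class `pulse_recording`.
#' @export
pulse_recording <- function(samples, sampling_rate = 12207, pulse_onsets,
                            stim_amplitude_mA = 1, phase_width_ms = 1.2,
                            stim_pair = c(NA, NA)) {
  samples <- rbind(samples)
  if (is.unsorted(pulse_onsets, strictly = TRUE))
    stop("pulse onsets must be strictly increasing", call. = FALSE)
  pre <- floor(0.050 * sampling_rate)
  npp <- floor(phase_width_ms / 1000 * sampling_rate)
  if (min(pulse_onsets) <= pre)
    stop("first pulse leaves less than 50 ms of pre-stimulus samples",
         call. = FALSE)
  if (max(pulse_onsets) + 2 * npp - 1 > ncol(samples))
    stop("last pulse extends beyond the record", call. = FALSE)
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         pulse_onsets = as.integer(pulse_onsets),
         stim_amplitude_mA = stim_amplitude_mA,
         phase_width_ms = phase_width_ms, stim_pair = stim_pair),
    class = "pulse_recording"
  )
}

#' @export
print.pulse_recording <- function(x, ...) {
  cat(sprintf(
    "<pulse_recording: %d channels, %d samples @ %g Hz, %d pulses, I0 = %g mA>\n",
    nrow(x$samples), ncol(x$samples), x$sampling_rate,
    length(x$pulse_onsets), x$stim_amplitude_mA
  ))
  invisible(x)
}

#' Samples per pulse phase
#' @param recording a [pulse_recording()] (or pass rate/width directly).
#' @return integer sample count, e.g. 14 for 1.2 ms at 12,207 Hz.
#' @export
samples_per_phase <- function(recording) {
  as.integer(floor(recording$phase_width_ms / 1000 * recording$sampling_rate))
}

#' Synthesize a biphasic pulse-train recording
#'
#' Each channel carries `n_pulses` rectangular biphasic pulses (first phase
#' at `+plateau`, second at `-plateau`, per channel), superposed on linear
#' baseline drift and white Gaussian noise. A clean (pulse-free) window of
#' at least 50 ms precedes every onset, as required by the baseline
#' correction.
#'
#' @param channel_plateaus named numeric vector: quasi-static plateau
#'   voltage per channel (volts).
#' @param n_pulses number of pulses (>= 1).
#' @param noise_sd white noise SD (volts).
#' @param drift_v_per_s linear baseline drift (volts/second).
#' @param sampling_rate Hz (default 12207).
#' @param phase_width_ms phase width (default 1.2 ms).
#' @param pre_gap_ms clean gap before each onset (>= 50 ms; default 55).
#' @param post_gap_ms gap after each pulse (default 5 ms).
#' @param stim_amplitude_mA recorded stimulation amplitude (metadata).
#' @param stim_pair cathode/anode labels (metadata).
#' @param seed RNG seed.
#' @return a [pulse_recording()].
#' @export
synthesize_recording <- function(channel_plateaus, n_pulses = 100,
                                 noise_sd = 0, drift_v_per_s = 0,
                                 sampling_rate = 12207, phase_width_ms = 1.2,
                                 pre_gap_ms = 55, post_gap_ms = 5,
                                 stim_amplitude_mA = 1,
                                 stim_pair = c(NA, NA), seed = 1L) {
  if (n_pulses < 1) stop("n_pulses must be >= 1", call. = FALSE)
  if (pre_gap_ms < 50) stop("pre-stimulus gap must be >= 50 ms", call. = FALSE)
  npp <- floor(phase_width_ms / 1000 * sampling_rate)
  if (npp < 8)
    stop(sprintf(
      "phase of %.4g ms at %g Hz yields only %d samples; at least 8 required",
      phase_width_ms, sampling_rate, npp), call. = FALSE)
  nch <- length(channel_plateaus)
  labels <- names(channel_plateaus)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nch))
  period <- floor((pre_gap_ms + post_gap_ms) / 1000 * sampling_rate) + 2L * npp
  onsets <- floor(pre_gap_ms / 1000 * sampling_rate) + 1L +
    (seq_len(n_pulses) - 1L) * period
  total <- onsets[n_pulses] + 2L * npp +
    floor(post_gap_ms / 1000 * sampling_rate)
  samples <- with_seed(seed, {
    m <- if (noise_sd > 0) {
      matrix(stats::rnorm(nch * total, sd = noise_sd), nch, total)
    } else matrix(0, nch, total)
    if (drift_v_per_s != 0) {
      m <- m + matrix(drift_v_per_s * (seq_len(total) - 1) / sampling_rate,
                      nch, total, byrow = TRUE)
    }
    m
  })
  ph1 <- as.vector(outer(0:(npp - 1L), onsets, "+"))
  ph2 <- ph1 + npp
  samples[, ph1] <- samples[, ph1] + channel_plateaus
  samples[, ph2] <- samples[, ph2] - channel_plateaus
  rownames(samples) <- labels
  pulse_recording(samples, sampling_rate, onsets, stim_amplitude_mA,
                  phase_width_ms, stim_pair)
}
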
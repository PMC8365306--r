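# Automated extraction of the quasi-static voltage from recorded pulse
# trains: baseline-correct each pulse to its 50-5 ms pre-stimulus mean,
# average all pulses per channel, detect phase boundaries from the +-1.5
# z-scored first difference, and average the steady-state plateau shortened
# by three samples on each side.

#' Baseline-correct each stimulation pulse
#'
#' Subtracts, per pulse and channel, the mean pre-stimulus signal over the
#' window from 50 to 5 ms before stimulation onset. The correction is
#' applied to the pulse's segment of the record (from 50 ms before its
#' onset up to 50 ms before the next), so a constant offset is removed
#' exactly and slow drift is removed up to its change within a pulse
#' period.
#'
#' @param recording a [pulse_recording()].
#' @return the corrected [pulse_recording()].
#' @export
baseline_correct <- function(recording) {
  fs <- recording$sampling_rate
  w0 <- floor(0.050 * fs)     # 50 ms before onset
  w1 <- floor(0.005 * fs)     # 5 ms before onset
  onsets <- recording$pulse_onsets
  n <- ncol(recording$samples)
  np <- length(onsets)
  if (onsets[1] - w0 < 1)
    stop("pulse 1 lacks 50 ms of pre-stimulus data", call. = FALSE)
  # per-pulse baselines (channels x pulses), accumulated without copying
  # the record once per pulse
  win_len <- w0 - w1
  bases <- matrix(0, nrow(recording$samples), np)
  for (k in seq_len(np)) {
    win <- (onsets[k] - w0):(onsets[k] - w1 - 1L)
    bases[, k] <- rowMeans(recording$samples[, win, drop = FALSE])
  }
  # segment ownership: pulse k owns [onset_k - 50 ms, onset_{k+1} - 50 ms)
  seg_starts <- onsets - w0
  segid <- findInterval(seq_len(n), seg_starts)
  owned <- segid >= 1L
  recording$samples[, owned] <- recording$samples[, owned, drop = FALSE] -
    bases[, segid[owned], drop = FALSE]
  recording
}

#' Time-locked mean over all stimulation pulses
#'
#' Averages identical windows around every pulse onset, channel-wise. With
#' n pulses the noise SD shrinks by about sqrt(n).
#'
#' @param recording a [pulse_recording()].
#' @param pre_ms,post_ms window margins around the biphasic pulse (ms).
#' @return channels x window matrix of mean waveforms with attributes
#'   `onset_index` (sample of pulse onset within the window) and
#'   `sampling_rate`.
#' @export
average_pulses <- function(recording, pre_ms = 10, post_ms = 4) {
  fs <- recording$sampling_rate
  npp <- samples_per_phase(recording)
  pre <- as.integer(floor(pre_ms / 1000 * fs))
  post <- as.integer(floor(post_ms / 1000 * fs))
  w <- pre + 2L * npp + post
  onsets <- recording$pulse_onsets
  if (min(onsets) - pre < 1 || max(onsets) + 2L * npp + post - 1L > ncol(recording$samples))
    stop("pulse window extends beyond the record", call. = FALSE)
  nch <- nrow(recording$samples)
  acc <- matrix(0, nch, w)
  for (on in onsets) {
    acc <- acc + recording$samples[, (on - pre):(on - pre + w - 1L), drop = FALSE]
  }
  out <- acc / length(onsets)
  rownames(out) <- rownames(recording$samples)
  attr(out, "onset_index") <- pre + 1L
  attr(out, "sampling_rate") <- fs
  attr(out, "samples_per_phase") <- npp
  out
}

#' Detect pulse-phase boundaries from a mean waveform
#'
#' The first difference of the mean waveform is converted to z-scores
#' (against its own mean and SD over the window); contiguous runs with
#' `|z| > z_threshold` mark the phase transitions. Phase onset is the first
#' sample after a supra-threshold run ends; phase offset the last sample
#' before the next run begins.
#'
#' @param mean_waveform one channel of [average_pulses()] output (numeric
#'   vector).
#' @param z_threshold threshold on the z-scored differentiated average
#'   (default 1.5).
#' @return integer matrix with rows `phase1`, `phase2` and columns
#'   `onset`, `offset` (sample indices into the waveform).
#' @export
detect_phases <- function(mean_waveform, z_threshold = 1.5) {
  d <- diff(mean_waveform)
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd == 0)
    stop("no pulse found: flat waveform (zero variance of the first difference)",
         call. = FALSE)
  z <- (d - mean(d)) / sdd
  supra <- abs(z) > z_threshold
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) < 3)
    stop("no pulse found: fewer than 3 supra-threshold transitions",
         call. = FALSE)
  # keep the 3 largest-|z| runs (onset, phase boundary, offset)
  if (length(runs) > 3) {
    peak <- vapply(runs, function(i) max(abs(z[starts[i]:ends[i]])), numeric(1))
    runs <- sort(runs[order(peak, decreasing = TRUE)[1:3]])
  }
  # diff index i spans samples (i, i+1): after run end at diff index e the
  # signal is steady from sample e+1
  b <- cbind(
    onset = ends[runs[1:2]] + 1L,
    offset = starts[runs[2:3]]
  )
  rownames(b) <- c("phase1", "phase2")
  if (any(b[, "offset"] < b[, "onset"]))
    stop("no pulse found: phase boundaries out of order", call. = FALSE)
  b
}

#' Mean steady-state plateau voltage
#'
#' Average of the first-phase plateau between detected onset and offset,
#' shortened by `trim` samples in each direction so the estimate stays
#' within the quasi-static interval.
#'
#' @param mean_waveform one channel's mean waveform.
#' @param boundaries output of [detect_phases()].
#' @param trim samples removed from each end (default 3).
#' @return plateau voltage (volts), signed as recorded.
#' @export
extract_plateau <- function(mean_waveform, boundaries, trim = 3L) {
  i0 <- boundaries["phase1", "onset"] + trim
  i1 <- boundaries["phase1", "offset"] - trim
  if (i1 < i0)
    stop(sprintf(
      "phase of %d samples leaves no plateau after trimming %d from each side",
      boundaries["phase1", "offset"] - boundaries["phase1", "onset"] + 1L, trim),
      call. = FALSE)
  mean(mean_waveform[i0:i1])
}

#' Extract quasi-static voltages from a pulse-train recording
#'
#' Full pipeline: baseline correction, pulse averaging, phase detection and
#' trimmed plateau averaging, per channel.
#'
#' @param recording a [pulse_recording()].
#' @param z_threshold threshold for [detect_phases()].
#' @param trim plateau trim (samples).
#' @return an `extracted_voltages` object: list with `voltages` (named, V),
#'   `boundaries` (per-channel phase boundary matrices) and `n_pulses_used`.
#' @export
extract_voltages <- function(recording, z_threshold = 1.5, trim = 3L) {
  rec <- baseline_correct(recording)
  avg <- average_pulses(rec)
  nch <- nrow(avg)
  voltages <- numeric(nch)
  bounds <- vector("list", nch)
  for (i in seq_len(nch)) {
    b <- detect_phases(avg[i, ], z_threshold)
    voltages[i] <- extract_plateau(avg[i, ], b, trim)
    bounds[[i]] <- b
  }
  names(voltages) <- rownames(avg)
  names(bounds) <- rownames(avg)
  structure(
    list(voltages = voltages, boundaries = bounds,
         n_pulses_used = length(recording$pulse_onsets)),
    class = "extracted_voltages"
  )
}

#' @export
print.extracted_voltages <- function(x, ...) {
  cat(sprintf("<extracted_voltages: %d channels from %d pulses>\n",
              length(x$voltages), x$n_pulses_used))
  invisible(x)
}
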
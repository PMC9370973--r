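# PPG/ACC filtering, ACC resampling, pulse segmentation, pulse normalization.

#' Band-pass filter a PPG signal
#'
#' Applies a second-order Butterworth band-pass filter with cut-off
#' frequencies of 0.5 and 12 Hz, the standard pre-processing band for wrist
#' PPG: it removes the DC baseline and slow drifts below the cardiac band and
#' attenuates high-frequency noise while keeping the systolic/diastolic
#' morphology (fundamental plus several harmonics).
#'
#' @param x numeric vector of raw PPG samples.
#' @param fs sampling frequency in Hz; must exceed 24 Hz so the upper cut-off
#'   lies below the Nyquist frequency.
#' @param zero_phase if `TRUE`, filter forward and backward
#'   ([signal::filtfilt()]) for zero phase lag; the default is a causal
#'   forward pass, matching an online pipeline.
#' @return filtered signal, same length as `x`.
#' @export
bandpass_ppg <- function(x, fs, zero_phase = FALSE) {
  apply_bandpass(x, fs, order = 2L, band = c(0.5, 12), zero_phase = zero_phase)
}

#' Band-pass filter an accelerometer channel
#'
#' Fourth-order Butterworth band-pass with cut-offs 0.025 and 10 Hz. The very
#' low high-pass edge removes the gravity component (and slow orientation
#' changes) from each axis before the vector magnitude is formed, while the
#' 10 Hz low-pass suppresses sensor noise above the range of voluntary
#' movement.
#'
#' @inheritParams bandpass_ppg
#' @export
bandpass_acc <- function(x, fs, zero_phase = FALSE) {
  apply_bandpass(x, fs, order = 4L, band = c(0.025, 10), zero_phase = zero_phase)
}

apply_bandpass <- function(x, fs, order, band, zero_phase = FALSE) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 2 * band[2L])
    stop_parameter("fs must exceed %g Hz (twice the upper cut-off); got %s",
                   2 * band[2L], format(fs))
  if (length(x) <= 3L * order)
    stop_integrity("signal too short to filter (%d samples)", length(x))
  flt <- signal::butter(order, band / (fs / 2), type = "pass")
  if (zero_phase) as.numeric(signal::filtfilt(flt, x))
  else as.numeric(signal::filter(flt, x))
}

#' Resample an accelerometer channel by linear interpolation
#'
#' Linearly interpolates a uniformly sampled sequence from `fs_in` to
#' `fs_out` Hz (typically 32 to 64 Hz, to match the PPG clock). Values at the
#' original sample instants are reproduced exactly; the output covers the same
#' time span as the input.
#'
#' @param x numeric vector (at least 2 samples).
#' @param fs_in,fs_out input and output sampling rates in Hz.
#' @return resampled numeric vector.
#' @export
resample_acc <- function(x, fs_in, fs_out) {
  if (fs_in <= 0 || fs_out <= 0) stop_parameter("sampling rates must be positive")
  if (length(x) < 2L) stop_integrity("need at least 2 samples to resample")
  if (fs_in == fs_out) return(x)
  t_in <- (seq_along(x) - 1) / fs_in
  t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_out)
  stats::approx(t_in, x, xout = t_out)$y
}

#' Z-score normalize one pulse
#'
#' Centers and scales a pulse to zero mean and unit standard deviation, using
#' the population convention (divide by N). Normalization makes
#' morphology-based quality indices comparable across pulses regardless of the
#' (optically arbitrary) PPG amplitude.
#'
#' @param x numeric vector, one segmented pulse (length >= 2).
#' @return normalized pulse of the same length.
#' @export
znorm_pulse <- function(x) {
  if (length(x) < 2L) stop_integrity("pulse shorter than 2 samples")
  s <- pop_sd(x)
  if (!is.finite(s) || s == 0)
    stop_degenerate("degenerate pulse: zero standard deviation")
  (x - mean(x)) / s
}

#' Detect systolic peaks and feet in filtered PPG
#'
#' Segments band-passed PPG into single pulses with a two-moving-average
#' event detector: the signal is clipped at zero and squared, and a
#' peak-scale moving average (window `w_peak`) is compared against a
#' beat-scale moving average (window `w_beat`) plus an offset
#' `beta * mean(squared signal)`. Contiguous regions where the fast average
#' exceeds the threshold are systolic candidate blocks; blocks shorter than
#' `w_peak` are discarded. The systolic peak is the maximum of the filtered
#' signal in each block and the systolic foot is the minimum between
#' consecutive peaks. Foot-to-foot intervals outside
#' `[min_interval, max_interval]` seconds (40-200 bpm by default) are dropped
#' as implausible.
#'
#' @param x filtered PPG signal.
#' @param fs sampling frequency in Hz.
#' @param w_peak,w_beat moving-average windows in seconds.
#' @param beta offset fraction of the mean squared signal.
#' @param min_interval,max_interval plausible foot-to-foot interval bounds in
#'   seconds.
#' @return a `data.frame` with 0-based integer columns `foot_sample`,
#'   `peak_sample`, `next_foot_sample`, one row per pulse (possibly 0 rows);
#'   pulse windows are half-open `[foot, next_foot)`.
#' @export
detect_pulses <- function(x, fs, w_peak = 0.111, w_beat = 0.667, beta = 0.02,
                          min_interval = 0.3, max_interval = 1.5) {
  if (length(x) < 2 * fs) stop_integrity("need at least 2 s of signal")
  sq <- pmax(x, 0)^2
  ma_peak <- moving_average(sq, round(w_peak * fs))
  ma_beat <- moving_average(sq, round(w_beat * fs))
  thr <- ma_beat + beta * mean(sq)
  on <- ma_peak > thr
  empty <- data.frame(foot_sample = integer(0), peak_sample = integer(0),
                      next_foot_sample = integer(0))
  if (!any(on)) return(empty)
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- cbind(starts[r$values], ends[r$values])
  blocks <- blocks[(blocks[, 2L] - blocks[, 1L] + 1L) >= round(w_peak * fs), ,
                   drop = FALSE]
  if (nrow(blocks) < 3L) return(empty)
  peaks <- vapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    b[1L] - 1L + which.max(x[b[1L]:b[2L]])
  }, integer(1))
  # foot k = minimum of the filtered signal between peaks k and k+1
  feet <- vapply(seq_len(length(peaks) - 1L), function(k) {
    peaks[k] - 1L + which.min(x[peaks[k]:peaks[k + 1L]])
  }, integer(1))
  n_pulse <- length(feet) - 1L
  out <- data.frame(
    foot_sample = feet[seq_len(n_pulse)] - 1L,        # to 0-based
    peak_sample = peaks[seq_len(n_pulse) + 1L] - 1L,
    next_foot_sample = feet[seq_len(n_pulse) + 1L] - 1L
  )
  ifi <- (out$next_foot_sample - out$foot_sample) / fs
  out <- out[ifi >= min_interval & ifi <= max_interval &
               out$peak_sample > out$foot_sample &
               out$peak_sample < out$next_foot_sample, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter and segment one recording
#'
#' Convenience wrapper: band-pass filters the PPG channel and runs
#' [detect_pulses()], returning the pulse table decorated with the subject id
#' and pulse start times together with the filtered signal (needed later for
#' the quality indices).
#'
#' @param rec a `ppg_recording` (see [read_recording()] / [synth_recording()]).
#' @param zero_phase passed to [bandpass_ppg()].
#' @param ... further arguments to [detect_pulses()].
#' @return list with `pulses` (pulse table `data.frame`), `ppg_filtered`, `fs`.
#' @export
segment_recording <- function(rec, zero_phase = FALSE, ...) {
  stopifnot(inherits(rec, "ppg_recording"))
  xf <- bandpass_ppg(rec$ppg, rec$fs_ppg, zero_phase = zero_phase)
  pt <- detect_pulses(xf, rec$fs_ppg, ...)
  pt <- data.frame(
    subject_id = rep(rec$subject_id, nrow(pt)),
    pulse_index = seq_len(nrow(pt)),
    pt,
    start_time_s = pt$foot_sample / rec$fs_ppg,
    activity_index = rep(NA_real_, nrow(pt)),
    activity_range = rep(NA_integer_, nrow(pt)),
    stringsAsFactors = FALSE
  )
  list(pulses = pt, ppg_filtered = xf, fs = rec$fs_ppg)
}

#' Extract the filtered and z-scored samples of one pulse
#'
#' @param ppg_filtered filtered PPG signal of the recording.
#' @param foot_sample,next_foot_sample 0-based half-open window bounds.
#' @return list with `filtered` and `norm` sample vectors.
#' @keywords internal
pulse_samples <- function(ppg_filtered, foot_sample, next_foot_sample) {
  xs <- ppg_filtered[(foot_sample + 1L):next_foot_sample]
  list(filtered = xs, norm = znorm_pulse(xs))
}
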
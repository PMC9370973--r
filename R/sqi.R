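# The nineteen per-pulse signal quality indices (SQIs): two from the
# accelerometer magnitude, seventeen from the PPG pulse (filtered or z-scored
# variant, depending on the index).

sqi_names <- c("Peak2peakACC", "MeanACC", "SigSim", "Entropy", "Kurtosis",
               "SNR", "RelPower", "Skewness", "ZR", "Amplitude", "Width",
               "TroughDepth", "MedianPulse", "MedianPulse_noZ",
               "MeanPulse_noZ", "StdPulse_noZ", "SNR_Moody", "Npeaks", "ZDR")

#' Similarity between consecutive pulses
#'
#' Pearson correlation between the current pulse and the previous one, after
#' linearly resampling the previous pulse to the current pulse's length.
#' Clean quasi-periodic PPG yields values near 1; motion-corrupted pulses
#' decorrelate from their neighbours.
#'
#' @param current,previous numeric pulse vectors (length >= 2 each).
#' @param floor value returned when either input has zero variance.
#' @return correlation in `[-1, 1]`.
#' @export
signal_similarity <- function(current, previous, floor = 0) {
  if (length(current) < 2L || length(previous) < 2L)
    stop_integrity("pulses must have at least 2 samples")
  prev_rs <- resample_to_length(previous, length(current))
  if (pop_sd(current) == 0 || pop_sd(prev_rs) == 0) return(floor)
  max(-1, min(1, stats::cor(current, prev_rs)))
}

#' Relative spectral power in the cardiac band
#'
#' Ratio of periodogram power in the 1-2.25 Hz band to the total power.
#' The pulse is zero-padded to 256 samples so the band edges are resolved
#' even for sub-second pulses.
#'
#' @param x z-scored pulse (length >= 8).
#' @param fs sampling rate in Hz.
#' @param band band limits in Hz.
#' @return ratio in `[0, 1]`.
#' @export
rel_power <- function(x, fs, band = c(1, 2.25)) {
  if (length(x) < 8L) stop_integrity("pulse too short for a spectral estimate")
  nfft <- max(256L, 2L^ceiling(log2(length(x))))
  xp <- c(x - mean(x), rep(0, nfft - length(x)))
  p <- Mod(stats::fft(xp))^2
  half <- p[seq_len(nfft %/% 2L + 1L)]
  f <- (seq_along(half) - 1) * fs / nfft
  tot <- sum(half)
  if (tot == 0) return(0)
  sum(half[f >= band[1L] & f <= band[2L]]) / tot
}

#' Count local maxima of a pulse
#'
#' Strict interior maxima; a flat-topped plateau counts once, at its first
#' sample. No prominence requirement, mirroring a default peak finder: a
#' clean pulse shows its systolic (and possibly diastolic) peaks, noisy
#' pulses many more.
#'
#' @param x numeric vector (length >= 3).
#' @return non-negative integer count.
#' @export
count_local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) stop_integrity("need at least 3 samples")
  d <- diff(x)
  # sign of slope, with zero runs inheriting the previous slope (plateaus)
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  sum(s[-length(s)] > 0 & s[-1L] < 0)
}

zero_crossings <- function(x) {
  s <- sign(x)
  # a sample exactly at 0 inherits the previous sign (no double counting)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

#' Zero-crossing rate
#'
#' Sign changes divided by (length - 1); samples exactly at zero inherit the
#' previous sign.
#'
#' @param x numeric vector (length >= 2).
#' @return rate in `[0, 1]`.
#' @export
zero_cross_rate <- function(x) {
  if (length(x) < 2L) stop_integrity("need at least 2 samples")
  zero_crossings(x) / (length(x) - 1L)
}

#' First-derivative zero-crossing rate
#'
#' Zero-crossing rate of the first difference; counts slope reversals, i.e.
#' waviness of the pulse.
#'
#' @param x numeric vector (length >= 3).
#' @return rate in `[0, 1]`.
#' @export
first_derivative_zcr <- function(x) {
  if (length(x) < 3L) stop_integrity("need at least 3 samples")
  zero_cross_rate(diff(x))
}

#' Histogram entropy of a pulse
#'
#' Shannon entropy (nats) of a 16-bin amplitude histogram of the z-scored
#' pulse over `[-4, 4]`; probabilities are normalized over the in-range mass.
#'
#' @param x z-scored pulse.
#' @param bins number of histogram bins.
#' @param lim symmetric amplitude limits.
#' @return entropy in nats, in `[0, log(bins)]`.
#' @export
pulse_entropy <- function(x, bins = 16L, lim = c(-4, 4)) {
  x <- pmin(pmax(x, lim[1L]), lim[2L])
  cuts <- seq(lim[1L], lim[2L], length.out = bins + 1L)
  h <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = bins)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Smoothing-residual signal-to-noise ratio
#'
#' Variance of the pulse over the variance of its high-frequency residual
#' (pulse minus a 125 ms moving-average smoothing), in dB. Clean pulses have
#' almost no residual and a high SNR.
#'
#' @param x z-scored pulse.
#' @param fs sampling rate in Hz.
#' @param smooth_s moving-average window in seconds.
#' @param ceiling_db cap returned when the residual power is zero.
#' @return SNR in dB.
#' @export
pulse_snr <- function(x, fs, smooth_s = 0.125, ceiling_db = 60) {
  resid <- x - moving_average(x, round(smooth_s * fs))
  vr <- pop_var(resid)
  if (vr == 0) return(ceiling_db)
  min(ceiling_db, 10 * log10(pop_var(x) / vr))
}

#' Template-residual signal-to-noise ratio
#'
#' Compares the pulse against a running template: both are linearly resampled
#' to a common length (64 samples) and the SNR is
#' `10 log10(power(template) / power(pulse - template))` dB. The template is an
#' exponentially weighted running mean (weight 0.1) of the z-scored pulses,
#' seeded with the first pulse of the recording.
#'
#' @param x z-scored pulse resampled to the template length.
#' @param template current template (same length).
#' @param ceiling_db cap for a zero residual.
#' @return SNR in dB.
#' @export
snr_moody <- function(x, template, ceiling_db = 60) {
  if (length(x) != length(template))
    stop_integrity("pulse and template lengths differ")
  resid <- x - template
  pr <- mean(resid^2)
  if (pr == 0) return(ceiling_db)
  min(ceiling_db, 10 * log10(mean(template^2) / pr))
}

#' Update the running pulse template
#'
#' @param template current template (or NULL before the first pulse).
#' @param x z-scored pulse resampled to the template length.
#' @param weight update weight of the new pulse.
#' @return updated template.
#' @export
update_template <- function(template, x, weight = 0.1) {
  if (is.null(template)) x else (1 - weight) * template + weight * x
}

#' Compute the 19 signal quality indices for one pulse
#'
#' Inputs are the filtered (un-normalized) pulse samples, the z-scored
#' variant, the previous pulse's z-scored samples (for SigSim; for the first
#' pulse of a recording the following pulse is used instead), the running
#' template, and the filtered ACC magnitude over the same half-open window.
#' `Amplitude`, `Width`, `TroughDepth` and the three `_noZ` statistics are
#' computed on the filtered pulse; everything else on the z-scored pulse.
#'
#' @param filtered filtered pulse samples over `[foot, next_foot)`.
#' @param norm z-scored pulse samples.
#' @param prev_norm previous (or fallback next) pulse's z-scored samples, or
#'   NULL.
#' @param template running 64-sample template (NULL for the first pulse).
#' @param acc_window filtered ACC magnitude over the pulse window (same 64 Hz
#'   index space), or NULL if no accelerometer is available.
#' @param fs sampling rate in Hz.
#' @param peak_offset 0-based offset of the systolic peak within the window.
#' @param trough_next filtered signal value at the next pulse's foot.
#' @param template_len common resampling length for the template comparison.
#' @return named numeric vector with the 19 indices.
#' @export
compute_sqi_vector <- function(filtered, norm, prev_norm, template,
                               acc_window, fs, peak_offset, trough_next,
                               template_len = 64L) {
  x64 <- resample_to_length(norm, template_len)
  out <- c(
    Peak2peakACC = if (is.null(acc_window)) NA_real_ else
      max(acc_window) - min(acc_window),
    MeanACC = if (is.null(acc_window)) NA_real_ else mean(acc_window),
    SigSim = if (is.null(prev_norm)) 0 else signal_similarity(norm, prev_norm),
    Entropy = pulse_entropy(norm),
    Kurtosis = moment_kurtosis(norm),
    SNR = pulse_snr(norm, fs),
    RelPower = rel_power(norm, fs),
    Skewness = moment_skewness(norm),
    ZR = zero_cross_rate(norm),
    Amplitude = filtered[peak_offset + 1L] - filtered[1L],
    Width = length(filtered) / fs,
    TroughDepth = abs(filtered[1L] - trough_next),
    MedianPulse = stats::median(norm),
    MedianPulse_noZ = stats::median(filtered),
    MeanPulse_noZ = mean(filtered),
    StdPulse_noZ = pop_sd(filtered),
    SNR_Moody = if (is.null(template)) 60 else snr_moody(x64, template),
    Npeaks = count_local_maxima(norm),
    ZDR = first_derivative_zcr(norm)
  )
  out[sqi_names]
}

#' Compute the SQI table for a recording
#'
#' Walks the pulse table in temporal order, maintaining the previous-pulse
#' reference and the exponentially weighted template, and returns one row of
#' 19 indices per requested pulse. Degenerate pulses (zero standard
#' deviation) are skipped with NA rows.
#'
#' @param ppg_filtered filtered PPG signal of the recording.
#' @param pulses pulse table for this recording (sorted by foot_sample).
#' @param acc_mag filtered ACC magnitude at the PPG rate (from
#'   [activity_profile()]), or NULL.
#' @param fs sampling rate in Hz.
#' @param subset optional logical/integer index of pulses for which the full
#'   feature row is needed; the z-score/template chain still runs over all
#'   pulses so SigSim and SNR_Moody see every predecessor.
#' @param template_weight exponential template update weight.
#' @return `data.frame` with the 19 SQI columns, rows aligned with `pulses`.
#' @export
compute_sqi_table <- function(ppg_filtered, pulses, acc_mag = NULL, fs = 64,
                              subset = NULL, template_weight = 0.1) {
  n <- nrow(pulses)
  want <- rep(FALSE, n)
  if (is.null(subset)) want[] <- TRUE else want[subset] <- TRUE
  out <- matrix(NA_real_, nrow = n, ncol = length(sqi_names),
                dimnames = list(NULL, sqi_names))
  if (n == 0L) return(as.data.frame(out))

  norms <- vector("list", n)
  for (i in seq_len(n)) {
    xs <- ppg_filtered[(pulses$foot_sample[i] + 1L):pulses$next_foot_sample[i]]
    norms[[i]] <- tryCatch(znorm_pulse(xs), ppgqc_degenerate_pulse_error =
                             function(e) NULL)
  }
  template <- NULL
  prev <- NULL
  for (i in seq_len(n)) {
    nrm <- norms[[i]]
    if (is.null(nrm)) next
    x64 <- resample_to_length(nrm, 64L)
    if (want[i]) {
      # first pulse of the recording: compare against the following pulse
      ref <- prev %||% (if (i < n) norms[[i + 1L]] else NULL)
      fseg <- ppg_filtered[(pulses$foot_sample[i] + 1L):pulses$next_foot_sample[i]]
      trough_next <- ppg_filtered[min(length(ppg_filtered),
                                      pulses$next_foot_sample[i] + 1L)]
      accw <- if (is.null(acc_mag)) NULL else
        acc_mag[pmin(length(acc_mag),
                     (pulses$foot_sample[i] + 1L):pulses$next_foot_sample[i])]
      out[i, ] <- compute_sqi_vector(
        filtered = fseg, norm = nrm, prev_norm = ref, template = template,
        acc_window = accw, fs = fs,
        peak_offset = pulses$peak_sample[i] - pulses$foot_sample[i],
        trough_next = trough_next)
    }
    template <- update_template(template, x64, template_weight)
    prev <- nrm
  }
  as.data.frame(out)
}
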
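# Accelerometer-derived activity index, quartile activity ranges, and the
# per-range stratified pulse sample.

#' Accelerometer vector magnitude
#'
#' Root-sum-square of the three (band-passed) accelerometer components,
#' sample by sample: `A_j = sqrt(x_j^2 + y_j^2 + z_j^2)`.
#'
#' @param x,y,z equal-length numeric vectors in g units.
#' @return non-negative numeric vector.
#' @export
acc_magnitude <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z))
    stop_integrity("accelerometer channels have mismatched lengths")
  sqrt(x^2 + y^2 + z^2)
}

#' Per-epoch standard deviation of the ACC magnitude
#'
#' Splits the magnitude series into consecutive epochs of `epoch_s` seconds
#' (N = epoch_s * fs samples) and returns the population standard deviation
#' (divide by N) of each epoch. A trailing partial epoch is discarded.
#'
#' @param a ACC magnitude series (g), sampled at `fs`.
#' @param fs sampling rate in Hz (64 after resampling).
#' @param epoch_s epoch length in seconds.
#' @return numeric vector of per-epoch sigma values (g).
#' @export
epoch_sigma <- function(a, fs, epoch_s = 5) {
  if (length(a) == 0L) stop_integrity("empty magnitude series")
  n <- round(epoch_s * fs)
  n_epochs <- length(a) %/% n
  if (n_epochs == 0L) return(numeric(0))
  m <- matrix(a[seq_len(n_epochs * n)], nrow = n)
  apply(m, 2L, pop_sd)
}

#' Minute-wise activity index
#'
#' Sums consecutive blocks of `epochs_per_minute` epoch sigmas (12 five-second
#' epochs = one minute). A trailing partial minute is discarded.
#'
#' @param sigma_epochs per-epoch standard deviations from [epoch_sigma()].
#' @param epochs_per_minute epochs per index value (M = 12).
#' @return numeric vector, one activity index value per complete minute.
#' @export
activity_index <- function(sigma_epochs, epochs_per_minute = 12) {
  if (length(sigma_epochs) < 1L) stop_parameter("need at least 1 epoch")
  n_min <- length(sigma_epochs) %/% epochs_per_minute
  if (n_min == 0L) return(numeric(0))
  m <- matrix(sigma_epochs[seq_len(n_min * epochs_per_minute)],
              nrow = epochs_per_minute)
  colSums(m)
}

#' Minute-wise activity profile of one recording
#'
#' Resamples each accelerometer component to `fs_out` Hz with linear
#' interpolation, band-pass filters it (0.025-10 Hz, removing gravity), forms
#' the vector magnitude and computes per-epoch sigmas and the minute-wise
#' activity index.
#'
#' @param rec a `ppg_recording` with ACC channels in g.
#' @param fs_out resampling target rate (Hz).
#' @param zero_phase passed to [bandpass_acc()].
#' @return object of class `activity_profile`: list with `sigma_epochs`,
#'   `a_index`, `epoch_s`, `epochs_per_minute`, `fs`, and `acc_mag` (the
#'   filtered magnitude at `fs_out`, reused by the ACC quality indices).
#' @export
activity_profile <- function(rec, fs_out = 64, zero_phase = FALSE) {
  stopifnot(inherits(rec, "ppg_recording"))
  ch <- lapply(list(rec$acc_x, rec$acc_y, rec$acc_z), function(v) {
    r <- resample_acc(v, rec$fs_acc, fs_out)
    bandpass_acc(r, fs_out, zero_phase = zero_phase)
  })
  a <- acc_magnitude(ch[[1L]], ch[[2L]], ch[[3L]])
  sig <- epoch_sigma(a, fs_out)
  structure(list(
    sigma_epochs = sig,
    a_index = activity_index(sig),
    epoch_s = 5, epochs_per_minute = 12, fs = fs_out,
    acc_mag = a
  ), class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("<activity_profile> %d epochs, %d minutes; Aind range [%.4g, %.4g] g\n",
              length(x$sigma_epochs), length(x$a_index),
              if (length(x$a_index)) min(x$a_index) else NA,
              if (length(x$a_index)) max(x$a_index) else NA))
  invisible(x)
}

#' Quartile activity-range boundaries
#'
#' Pools activity-index values from all recordings and returns their 25th,
#' 50th and 75th percentiles (linear interpolation between order statistics,
#' quantile type 7). The four activity ranges are then
#' AR0 = \[min, Q1\], AR1 = (Q1, Q2\], AR2 = (Q2, Q3\], AR3 = (Q3, max\].
#'
#' @param all_aind pooled activity-index values (>= 4).
#' @return numeric vector of the three non-decreasing boundaries.
#' @export
define_activity_ranges <- function(all_aind) {
  all_aind <- all_aind[!is.na(all_aind)]
  if (length(all_aind) < 4L)
    stop_parameter("need at least 4 pooled activity-index values")
  unname(stats::quantile(all_aind, probs = c(0.25, 0.5, 0.75), type = 7))
}

#' Assign activity ranges to activity-index values
#'
#' Right-closed interval convention: values <= Q1 fall in AR0, values in
#' (Q1, Q2\] in AR1, (Q2, Q3\] in AR2, above Q3 in AR3.
#'
#' @param aind activity-index values.
#' @param boundaries three quartile boundaries from [define_activity_ranges()].
#' @return integer vector of ranges in `0:3` (NA stays NA).
#' @export
assign_activity_range <- function(aind, boundaries) {
  if (length(boundaries) != 3L || is.unsorted(boundaries))
    stop_parameter("boundaries must be 3 non-decreasing values")
  r <- findInterval(aind, boundaries, left.open = TRUE)
  as.integer(ifelse(is.na(aind), NA_integer_, r))
}

#' Attach activity index and range to each pulse
#'
#' A pulse belongs to the minute containing its systolic foot; it inherits
#' that minute's activity index and (if boundaries are given) activity range.
#' Pulses whose foot falls in a discarded trailing partial minute get NA.
#'
#' @param pulses pulse table (from [segment_recording()]).
#' @param profile `activity_profile` of the same recording.
#' @param boundaries optional pooled quartile boundaries.
#' @param fs PPG sampling rate used for the pulse sample indices.
#' @return the pulse table with `activity_index` (and `activity_range`) filled.
#' @export
assign_pulse_ar <- function(pulses, profile, boundaries = NULL, fs = 64) {
  stopifnot(inherits(profile, "activity_profile"))
  minute <- floor((pulses$foot_sample / fs) / 60)
  if (nrow(pulses) && any(minute < 0))
    stop_integrity("pulse before recording start")
  idx <- minute + 1L
  aind <- rep(NA_real_, nrow(pulses))
  ok <- idx >= 1L & idx <= length(profile$a_index)
  aind[ok] <- profile$a_index[idx[ok]]
  pulses$activity_index <- aind
  if (!is.null(boundaries))
    pulses$activity_range <- assign_activity_range(aind, boundaries)
  pulses
}

#' Stratified random pulse sample
#'
#' Draws `per_range` pulses uniformly without replacement from each
#' (recording, activity range) stratum; strata with fewer pulses contribute
#' all of them with a warning. Sampling is deterministic given `seed`:
#' each subject uses its own seed substream so results do not depend on
#' processing order.
#'
#' @param pulses pooled pulse table with `activity_range` assigned.
#' @param per_range pulses to draw per range per recording.
#' @param seed integer seed.
#' @return the sampled subset, sorted by (subject_id, foot_sample).
#' @export
stratified_sample <- function(pulses, per_range = 100, seed = 1) {
  pulses <- pulses[!is.na(pulses$activity_range), , drop = FALSE]
  subjects <- sort(unique(pulses$subject_id))
  keep <- logical(nrow(pulses))
  for (si in seq_along(subjects)) {
    set.seed(derive_seed(seed, si))
    for (r in 0:3) {
      idx <- which(pulses$subject_id == subjects[si] & pulses$activity_range == r)
      if (length(idx) == 0L) next
      if (length(idx) < per_range) {
        warning(sprintf("subject %s range %d: only %d pulses (< %d), taking all",
                        subjects[si], r, length(idx), per_range))
        keep[idx] <- TRUE
      } else {
        keep[sample(idx, per_range)] <- TRUE
      }
    }
  }
  out <- pulses[keep, , drop = FALSE]
  out <- out[order(out$subject_id, out$foot_sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}
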
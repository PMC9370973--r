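# Synthetic wrist PPG + accelerometer cohort with ground-truth pulse quality.
#
# Each beat is a systolic plus (optionally) diastolic Gaussian wave over a
# heart-period window; band-limited noise is added with a per-minute standard
# deviation tied to the scheduled motion level, and the accelerometer carries
# a gravity vector plus burst oscillations at the same motion level, so motion
# simultaneously raises the activity index and corrupts PPG morphology.

#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions the pipeline assumes: 31 subjects,
#' 30 minutes each (a desk-scale stand-in for day-long wear), heart rates
#' around 72 bpm, a two-wave pulse morphology, four scheduled motion levels
#' per recording occupying roughly equal time so the pooled quartile activity
#' ranges are all populated, and noise/diastolic-suppression rules that
#' partition beats into Bad/Fair/Excellent with prevalences near 48/37/15%.
#'
#' @param n_subjects number of recordings.
#' @param duration_s recording length per subject (whole minutes).
#' @param fs_ppg,fs_acc sampling rates (Hz).
#' @param hr_mean,hr_sd between-subject heart-rate law (bpm).
#' @param hr_jitter lognormal sd of the per-beat period jitter.
#' @param sys_amp,sys_amp_sd systolic wave amplitude law (arbitrary units).
#' @param sys_center,sys_width systolic Gaussian center/width as fractions of
#'   the beat period.
#' @param dia_ratio,dia_center,dia_width diastolic wave amplitude ratio and
#'   center/width fractions.
#' @param dia_retain_prob probability a beat keeps its diastolic wave.
#' @param level_noise_sd additive PPG noise sd (units of `sys_amp`) for the
#'   four motion levels.
#' @param noise_jitter_sd lognormal sd of the per-minute noise jitter.
#' @param theta_e,theta_f noise-to-signal thresholds of the label rule: a beat
#'   is Excellent when its noise-to-signal ratio is below `theta_e` and the
#'   diastolic wave is retained, Fair when the ratio is below `theta_f`,
#'   otherwise Bad.
#' @param level_acc_amp accelerometer burst amplitude (g) per motion level.
#' @param acc_jitter_sd lognormal sd of the per-minute burst-amplitude jitter.
#' @param acc_noise_sd accelerometer sensor noise sd (g per axis).
#' @param motion_freq burst oscillation frequency range (Hz).
#' @param rater_confusion 3x3 row-stochastic matrix; row = true class (B,F,E),
#'   column = probability a rater votes B/F/E.
#' @param start_time recording start, seconds since epoch.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 31, duration_s = 1800,
                         fs_ppg = 64, fs_acc = 32,
                         hr_mean = 72, hr_sd = 5, hr_jitter = 0.03,
                         sys_amp = 1, sys_amp_sd = 0.05,
                         sys_center = 0.30, sys_width = 0.10,
                         dia_ratio = 0.35, dia_center = 0.62, dia_width = 0.14,
                         dia_retain_prob = 0.62,
                         level_noise_sd = c(0.03, 0.15, 0.5, 0.8),
                         noise_jitter_sd = 0.2,
                         theta_e = 0.08, theta_f = 0.30,
                         level_acc_amp = c(0, 0.05, 0.25, 0.9),
                         acc_jitter_sd = 0.2, acc_noise_sd = 0.004,
                         motion_freq = c(2, 3.5),
                         rater_confusion = default_rater_confusion(),
                         start_time = 1.6e9) {
  cfg <- as.list(environment())
  if (n_subjects < 1 || duration_s < 120 || fs_ppg <= 0 || fs_acc <= 0 ||
      hr_mean <= 0 || sys_amp <= 0 || sys_width <= 0 || dia_width <= 0)
    stop_parameter("rates, amplitudes and durations must be positive")
  if (!(theta_e < theta_f))
    stop_parameter("label rule requires theta_e < theta_f (got %g >= %g)",
                   theta_e, theta_f)
  if (length(level_noise_sd) != 4L || length(level_acc_amp) != 4L)
    stop_parameter("level_noise_sd and level_acc_amp must have 4 entries")
  rc <- as.matrix(rater_confusion)
  if (!all(dim(rc) == c(3L, 3L)) || any(rc < 0) ||
      max(abs(rowSums(rc) - 1)) > 1e-8)
    stop_parameter("rater_confusion must be a 3x3 row-stochastic matrix")
  structure(cfg, class = "synth_config")
}

#' @rdname synth_config
#' @export
default_rater_confusion <- function() {
  matrix(c(0.90, 0.08, 0.02,
           0.05, 0.90, 0.05,
           0.02, 0.08, 0.90),
         nrow = 3L, byrow = TRUE,
         dimnames = list(c("B", "F", "E"), c("B", "F", "E")))
}

#' Generate one synthetic recording with ground truth
#'
#' Deterministic given `(seed, subject_index)`. Returns the raw recording
#' (the PPG noise and ACC bursts share the per-minute motion schedule) and a
#' ground-truth beat table with the simulated foot/peak sample of each beat,
#' its minute, noise-to-signal ratio, diastolic retention flag and B/F/E
#' label derived from the generation parameters (not from re-detection).
#'
#' @param config a `synth_config`.
#' @param subject_id subject identifier string.
#' @param seed master integer seed.
#' @param subject_index integer key for the subject's seed substream.
#' @return list with `recording` (a `ppg_recording`), `beats` (data.frame),
#'   and `minute_levels` (integer motion level per minute).
#' @export
synth_recording <- function(config, subject_id, seed = 1, subject_index = 1) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(seed, subject_index))
  fs <- config$fs_ppg
  n <- round(config$duration_s * fs)
  n_min <- floor(config$duration_s / 60)

  # motion schedule: near-equal minutes per level, order shuffled per subject
  levels_min <- sample(rep(0:3, length.out = n_min))
  noise_sd_min <- config$level_noise_sd[levels_min + 1L] *
    exp(stats::rnorm(n_min, 0, config$noise_jitter_sd))

  # beat train
  hr <- min(100, max(50, stats::rnorm(1, config$hr_mean, config$hr_sd)))
  feet_t <- numeric(0)
  periods <- numeric(0)
  t <- 0
  repeat {
    per <- 60 / hr * exp(stats::rnorm(1, 0, config$hr_jitter))
    per <- min(1.4, max(0.35, per))
    if (t + per > config$duration_s) break
    feet_t <- c(feet_t, t)
    periods <- c(periods, per)
    t <- t + per
  }
  n_beats <- length(feet_t)
  amp <- pmax(0.5, stats::rnorm(n_beats, config$sys_amp, config$sys_amp_sd))
  retained <- stats::runif(n_beats) < config$dia_retain_prob
  minute <- pmin(floor(feet_t / 60), n_min - 1L)

  ppg <- numeric(n)
  peak_sample <- integer(n_beats)
  foot_sample <- as.integer(round(feet_t * fs))
  for (b in seq_len(n_beats)) {
    i0 <- foot_sample[b] + 1L
    i1 <- min(n, as.integer(round((feet_t[b] + periods[b]) * fs)))
    tt <- ((i0:i1) - 1) / fs
    ph <- (tt - feet_t[b]) / periods[b]
    w <- amp[b] * (exp(-0.5 * ((ph - config$sys_center) / config$sys_width)^2) +
                     (if (retained[b]) config$dia_ratio else 0) *
                       exp(-0.5 * ((ph - config$dia_center) / config$dia_width)^2))
    ppg[i0:i1] <- ppg[i0:i1] + w
    peak_sample[b] <- i0 - 1L + which.max(w) - 1L  # 0-based
  }

  # band-limited noise, per-minute envelope
  any_noise <- any(noise_sd_min > 0)
  if (any_noise) {
    wn <- bandpass_ppg(stats::rnorm(n), fs)
    wn <- wn / stats::sd(wn)
    env <- rep(noise_sd_min, each = 60 * fs)[seq_len(n)]
    ppg <- ppg + wn * env
  }

  nsr <- noise_sd_min[minute + 1L] / amp
  label <- ifelse(nsr < config$theta_e & retained, "E",
                  ifelse(nsr < config$theta_f, "F", "B"))

  # accelerometer: gravity + per-minute burst oscillation + sensor noise
  n_acc <- round(config$duration_s * config$fs_acc)
  t_acc <- (seq_len(n_acc) - 1) / config$fs_acc
  grav <- stats::rnorm(3)
  grav <- grav / sqrt(sum(grav^2))
  acc <- matrix(rep(grav, each = n_acc), ncol = 3L)
  min_of_sample <- pmin(floor(t_acc / 60), n_min - 1L)
  for (m in seq_len(n_min) - 1L) {
    lv <- levels_min[m + 1L]
    if (config$level_acc_amp[lv + 1L] <= 0) next
    a <- config$level_acc_amp[lv + 1L] * exp(stats::rnorm(1, 0, config$acc_jitter_sd))
    f <- stats::runif(1, config$motion_freq[1L], config$motion_freq[2L])
    phi <- stats::runif(1, 0, 2 * pi)
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    idx <- which(min_of_sample == m)
    osc <- a * sin(2 * pi * f * t_acc[idx] + phi)
    acc[idx, ] <- acc[idx, ] + outer(osc, dir)
  }
  acc <- acc + matrix(stats::rnorm(3 * n_acc, 0, config$acc_noise_sd), ncol = 3L)

  rec <- new_recording(subject_id, ppg = ppg, fs_ppg = fs,
                       acc_x = acc[, 1L], acc_y = acc[, 2L], acc_z = acc[, 3L],
                       fs_acc = config$fs_acc, acc_scale = 64,
                       start_time = config$start_time)
  beats <- data.frame(
    subject_id = subject_id, beat = seq_len(n_beats),
    foot_sample = foot_sample, peak_sample = peak_sample,
    period_s = periods, minute = minute, nsr = nsr,
    dia_retained = retained, label = label, stringsAsFactors = FALSE)
  list(recording = rec, beats = beats, minute_levels = levels_min)
}

#' Generate the full synthetic cohort
#'
#' One call of [synth_recording()] per subject, each on its own deterministic
#' seed substream.
#'
#' @param config a `synth_config`.
#' @param seed master integer seed.
#' @return object of class `synth_cohort`: list with `recordings`,
#'   `beats` (both per-subject lists), `config`, `seed`.
#' @export
synth_cohort <- function(config = synth_config(), seed = 1) {
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  out <- lapply(seq_along(subjects), function(i)
    synth_recording(config, subjects[i], seed = seed, subject_index = i))
  structure(list(
    recordings = lapply(out, `[[`, "recording"),
    beats = lapply(out, `[[`, "beats"),
    subjects = subjects, config = config, seed = seed
  ), class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d subjects, %.0f s each, seed %d\n",
              length(x$recordings), x$config$duration_s, x$seed))
  invisible(x)
}

#' Simulate rater votes from ground-truth labels
#'
#' Each of `n_raters` raters votes independently: the vote is drawn from the
#' confusion-matrix row of the pulse's true class. An identity matrix yields
#' unanimous (perfect-kappa) raters.
#'
#' @param truth character vector of true B/F/E labels.
#' @param confusion 3x3 row-stochastic confusion matrix (rows/cols B,F,E).
#' @param n_raters number of raters.
#' @param seed integer seed.
#' @return data.frame with columns `rater_1` ... `rater_<n>`.
#' @export
synth_rater_votes <- function(truth, confusion = default_rater_confusion(),
                              n_raters = 3, seed = 1) {
  lv <- c("B", "F", "E")
  confusion <- as.matrix(confusion)
  votes <- lapply(seq_len(n_raters), function(r) {
    set.seed(derive_seed(seed, 500L + r))
    vapply(truth, function(tl)
      sample(lv, 1L, prob = confusion[match(tl, lv), ]), character(1),
      USE.NAMES = FALSE)
  })
  names(votes) <- paste0("rater_", seq_len(n_raters))
  as.data.frame(votes, stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to disk
#'
#' Emits per-subject PPG/ACC CSV files in the requested dialect plus a
#' ground-truth beat label table, so the file-based CLI pipeline can run on
#' purely synthetic data.
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if missing).
#' @param dialect `"e4"`, `"generic"`, or `"both"`.
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir, dialect = c("e4", "generic", "both")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dialects <- if (dialect == "both") c("e4", "generic") else dialect
  files <- character(0)
  for (i in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[i]]
    for (d in dialects) {
      pp <- file.path(dir, sprintf("%s_ppg_%s.csv", rec$subject_id, d))
      ap <- file.path(dir, sprintf("%s_acc_%s.csv", rec$subject_id, d))
      write_recording(rec, pp, ap, dialect = d)
      files <- c(files, pp, ap)
    }
    bp <- file.path(dir, sprintf("%s_beats.csv", rec$subject_id))
    utils::write.csv(cohort$beats[[i]], bp, row.names = FALSE)
    files <- c(files, bp)
  }
  invisible(files)
}
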
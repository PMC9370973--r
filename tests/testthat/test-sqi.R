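test_that("signal similarity resamples and correlates as computed by hand", {
  x <- c(0.1, 0.9, 0.3, 0.2, 0.5)
  expect_equal(signal_similarity(x, x), 1)
  expect_equal(signal_similarity(x, -x), -1)
  # hand oracle: linear interpolation of the previous pulse, then Pearson
  cur <- c(0, 1, 0)
  prev <- c(0, 1, 0, 0)
  prev_rs <- approx(1:4, prev, n = 3)$y
  expect_equal(signal_similarity(cur, prev), cor(cur, prev_rs))
  set.seed(13)
  a <- random_pulse(50); b <- random_pulse(64)
  expect_equal(signal_similarity(a, b), cor(a, approx(1:64, b, n = 50)$y),
               tolerance = 1e-12)
  # zero variance falls back to the configured floor
  expect_equal(signal_similarity(rep(1, 10), random_pulse(10)), 0)
})

test_that("relative power isolates the 1-2.25 Hz band", {
  fs <- 64
  t <- (0:(4 * fs - 1)) / fs
  expect_gte(rel_power(sin(2 * pi * 1.5 * t), fs), 0.9)
  expect_lte(rel_power(sin(2 * pi * 5 * t), fs), 0.1)
  mixed <- sin(2 * pi * 1.5 * t) + sin(2 * pi * 5 * t)
  expect_equal(rel_power(mixed, fs), 0.5, tolerance = 0.1)
})

test_that("local maxima counting applies the first-sample plateau rule", {
  expect_equal(count_local_maxima(c(0, 1, 0, 1, 0)), 2)
  expect_equal(count_local_maxima(1:10), 0)
  expect_equal(count_local_maxima(c(0, 1, 1, 0)), 1)
  expect_equal(count_local_maxima(c(0, 2, 2, 2, 1, 3, 0)), 2)
})

test_that("zero-crossing rates handle exact zeros and bounds", {
  expect_equal(zero_cross_rate(rep(c(1, -1), 10)), 1)
  expect_equal(zero_cross_rate(abs(random_pulse(30)) + 0.1), 0)
  # a zero sample inherits the previous sign: no double counting
  expect_equal(zero_cross_rate(c(1, 0, -1)), 0.5)
  # single-peak triangle: exactly one derivative sign change
  tri <- c(0, 1, 2, 3, 2, 1, 0)
  expect_equal(first_derivative_zcr(tri), 1 / 5)
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(40)
    expect_gte(zero_cross_rate(x), 0); expect_lte(zero_cross_rate(x), 1)
    expect_gte(first_derivative_zcr(x), 0); expect_lte(first_derivative_zcr(x), 1)
  }
})

test_that("moment skewness/kurtosis match explicit formula oracles", {
  set.seed(15)
  for (i in 1:5) {
    x <- rnorm(100)^2
    n <- length(x); m <- sum(x) / n
    m2 <- sum((x - m)^2) / n; m3 <- sum((x - m)^3) / n; m4 <- sum((x - m)^4) / n
    expect_equal(moment_skewness(x), m3 / m2^1.5, tolerance = 1e-9)
    expect_equal(moment_kurtosis(x), m4 / m2^2, tolerance = 1e-9)
  }
})

test_that("template SNR behaves like a matched-residual ratio", {
  set.seed(16)
  tpl <- znorm_pulse(sin(seq(0, 2 * pi, length.out = 64)))
  expect_equal(snr_moody(tpl, tpl), 60)
  # matched-power noise -> about 0 dB
  vals <- replicate(40, {
    noise <- rnorm(64) * sqrt(mean(tpl^2))
    snr_moody(tpl + noise, tpl)
  })
  expect_lt(abs(mean(vals)), 1)
  # uncorrelated equal-power pulse -> below 3 dB
  vals2 <- replicate(40, snr_moody(rnorm(64) * sqrt(mean(tpl^2)), tpl))
  expect_lt(mean(vals2), 3)
  expect_error(snr_moody(rnorm(10), tpl), class = "ppgqc_integrity_error")
})

test_that("entropy and smoothing SNR separate clean from noisy pulses", {
  t <- seq(0, 1, length.out = 64)
  clean <- znorm_pulse(exp(-0.5 * ((t - 0.3) / 0.1)^2))
  noisy <- znorm_pulse(rnorm(64))
  expect_gt(pulse_snr(clean, 64), pulse_snr(noisy, 64))
  expect_gte(pulse_entropy(clean), 0)
  expect_lte(pulse_entropy(clean), log(16))
})

test_that("z-scored features are affine-invariant; _noZ and ACC features are not", {
  syn <- synth_recording(synth_config(n_subjects = 1, duration_s = 300),
                         "S1", seed = 17)
  pr <- process_recording(syn$recording)
  sq1 <- compute_sqi_table(pr$ppg_filtered, pr$pulses,
                           acc_mag = pr$profile$acc_mag, fs = 64,
                           subset = 2:11)
  sq2 <- compute_sqi_table(3.7 * pr$ppg_filtered + 11, pr$pulses,
                           acc_mag = pr$profile$acc_mag, fs = 64,
                           subset = 2:11)
  inv <- c("SigSim", "Entropy", "Kurtosis", "SNR", "RelPower", "Skewness",
           "ZR", "ZDR", "Npeaks", "MedianPulse", "SNR_Moody")
  for (f in inv)
    expect_equal(sq2[2:11, f], sq1[2:11, f], tolerance = 1e-6, label = f)
  for (f in c("Amplitude", "StdPulse_noZ"))
    expect_equal(sq2[2:11, f], 3.7 * sq1[2:11, f], tolerance = 1e-6, label = f)
  expect_equal(sq2$MeanPulse_noZ[2:11], 3.7 * sq1$MeanPulse_noZ[2:11] + 11,
               tolerance = 1e-6)
  expect_equal(sq2$Width[2:11], sq1$Width[2:11])
})

test_that("pulse-level oracles hold on generator ground truth", {
  # noise-free two-wave pulse with a still wrist
  syn <- synth_recording(clean_config(duration_s = 120, hr = 66), "S1", seed = 18)
  pr <- process_recording(syn$recording)
  # skip the first minute: the 0.025 Hz ACC high-pass is still settling the
  # gravity step there
  rows <- 80:105
  sq <- compute_sqi_table(pr$ppg_filtered, pr$pulses,
                          acc_mag = pr$profile$acc_mag, fs = 64,
                          subset = rows)
  expect_true(all(sq$Npeaks[rows] == 2))
  expect_true(all(sq$Peak2peakACC[rows] < 0.01))
  expect_true(all(sq$RelPower[rows] > 0.5))
  expect_true(all(sq$SigSim[rows] > 0.97))

  # white-noise "pulse": many maxima, similarity near zero
  set.seed(19)
  hits <- replicate(30, {
    p <- znorm_pulse(rnorm(64))
    q <- znorm_pulse(rnorm(64))
    c(count_local_maxima(p), abs(signal_similarity(p, q)))
  })
  expect_gt(median(hits[1, ]), 10)
  expect_gt(mean(hits[2, ] < 0.5), 0.9)
})

test_that("SQI distributions separate the quality classes on the corpus", {
  ds <- small_dataset()
  f <- ds$features
  med <- function(col, lab) median(f[[col]][f$truth == lab])
  expect_gt(med("Npeaks", "B"), med("Npeaks", "E"))
  expect_gt(med("SigSim", "E"), med("SigSim", "B"))
  expect_gt(med("Peak2peakACC", "B"), med("Peak2peakACC", "E"))
})

test_that("the SQI vector is complete and first-pulse fallbacks work", {
  syn <- synth_recording(clean_config(duration_s = 120), "S1", seed = 20)
  pr <- process_recording(syn$recording)
  sq <- compute_sqi_table(pr$ppg_filtered, pr$pulses,
                          acc_mag = pr$profile$acc_mag, fs = 64)
  expect_equal(ncol(sq), 19L)
  expect_false(anyNA(sq))
  # first pulse: SigSim compares against the following pulse, template seeds
  expect_gt(sq$SigSim[1], 0.9)
  expect_equal(sq$SNR_Moody[1], 60)
})
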
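test_that("vector magnitude and epoch sigma follow their formulas", {
  expect_equal(acc_magnitude(3, 4, 0), 5)
  expect_equal(acc_magnitude(0, 0, 0), 0)
  expect_equal(acc_magnitude(1, 2, 2), 3)
  expect_error(acc_magnitude(1:3, 1:2, 1:3), class = "ppgqc_integrity_error")

  expect_equal(epoch_sigma(rep(0.7, 320), 64), 0)
  expect_equal(epoch_sigma(rep(c(1, -1), 160), 64), 1)
  # brute-force population sd oracle on one random epoch
  set.seed(4)
  a <- rnorm(320)
  expect_equal(epoch_sigma(a, 64), sqrt(mean((a - mean(a))^2)), tolerance = 1e-12)
  # trailing partial epoch discarded
  expect_length(epoch_sigma(rnorm(700), 64), 2L)
  expect_error(epoch_sigma(numeric(0), 64), class = "ppgqc_integrity_error")
})

test_that("the activity index sums 12 epochs per minute", {
  expect_equal(activity_index(rep(0.5, 12)), 6.0)
  expect_equal(activity_index(rep(0, 24)), c(0, 0))
  expect_equal(activity_index((1:12) * 0.01), 0.78)
  # partial minute discarded
  expect_length(activity_index(rep(1, 30)), 2L)
  # sum decomposition over complete minutes
  set.seed(5)
  s <- abs(rnorm(36))
  expect_equal(sum(activity_index(s)), sum(s), tolerance = 1e-9)
})

test_that("quartile ranges use type-7 percentiles with right-closed brackets", {
  b <- define_activity_ranges(1:8)
  # brute-force order-statistic oracle for n = 8, type 7
  expect_equal(b, c(2.75, 4.5, 6.25))
  ar <- assign_activity_range(1:8, b)
  expect_equal(as.integer(table(ar)), rep(2L, 4))

  expect_equal(unique(assign_activity_range(rep(3, 10),
                                            define_activity_ranges(rep(3, 10)))), 0L)
  b2 <- define_activity_ranges(c(seq(0, 0.04, length.out = 20),
                                 seq(0.4, 1.3, length.out = 20),
                                 seq(2, 6.7, length.out = 20)))
  expect_false(is.unsorted(b2))

  expect_error(define_activity_ranges(c(1, 2, 3)), class = "ppgqc_parameter_error")
  # boundary values land in the lower (right-closed) range
  expect_equal(assign_activity_range(2.75, b), 0L)
  expect_equal(assign_activity_range(2.76, b), 1L)
  expect_equal(assign_activity_range(6.26, b), 3L)
})

test_that("pooled assignment puts about a quarter of values in each range", {
  set.seed(6)
  v <- rexp(4000)
  ar <- assign_activity_range(v, define_activity_ranges(v))
  expect_equal(as.integer(table(ar)) / 4000, rep(0.25, 4), tolerance = 0.01)
})

test_that("activity profile scales linearly with the ACC channels", {
  syn <- synth_recording(synth_config(n_subjects = 1, duration_s = 300),
                         "S1", seed = 8)
  rec <- syn$recording
  p1 <- activity_profile(rec)
  rec2 <- rec
  rec2$acc_x <- 2 * rec$acc_x; rec2$acc_y <- 2 * rec$acc_y
  rec2$acc_z <- 2 * rec$acc_z
  p2 <- activity_profile(rec2)
  expect_equal(p2$sigma_epochs, 2 * p1$sigma_epochs, tolerance = 1e-8)
  expect_equal(p2$a_index, 2 * p1$a_index, tolerance = 1e-8)
  # Aind decomposes into its epoch sigmas
  expect_equal(p1$a_index[1], sum(p1$sigma_epochs[1:12]), tolerance = 1e-9)
})

test_that("burst minutes carry a higher activity index than rest minutes", {
  syn <- synth_recording(synth_config(n_subjects = 1, duration_s = 600),
                         "S1", seed = 10)
  prof <- activity_profile(syn$recording)
  lv <- syn$minute_levels[seq_along(prof$a_index)]
  expect_gt(mean(prof$a_index[lv == 3]), mean(prof$a_index[lv == 0]))
  expect_gt(mean(prof$a_index[lv >= 2]), mean(prof$a_index[lv <= 1]))
})

test_that("pulses inherit their foot minute's index and range", {
  syn <- synth_recording(synth_config(n_subjects = 1, duration_s = 300),
                         "S1", seed = 12)
  pr <- process_recording(syn$recording)
  b <- define_activity_ranges(pr$profile$a_index)
  pulses <- assign_pulse_ar(pr$pulses, pr$profile, boundaries = b, fs = 64)
  minute <- floor(pulses$start_time_s / 60) + 1L
  expect_equal(pulses$activity_index, pr$profile$a_index[minute])
  # a pulse with the minimum Aind minute gets range 0
  at_min <- !is.na(pulses$activity_index) &
    pulses$activity_index == min(pr$profile$a_index)
  expect_equal(unique(pulses$activity_range[at_min]), 0L)
})

test_that("stratified sampling is exact, deterministic, and warns when short", {
  pool <- do.call(rbind, lapply(c("A", "B"), function(s) {
    data.frame(subject_id = s, pulse_index = 1:600,
               foot_sample = seq(0, by = 50, length.out = 600),
               peak_sample = seq(20, by = 50, length.out = 600),
               next_foot_sample = seq(49, by = 50, length.out = 600),
               start_time_s = 0, activity_index = runif(600),
               activity_range = rep(0:3, each = 150))
  }))
  s1 <- stratified_sample(pool, per_range = 100, seed = 7)
  expect_equal(nrow(s1), 800L)
  expect_true(all(table(s1$subject_id, s1$activity_range) == 100))
  s2 <- stratified_sample(pool, per_range = 100, seed = 7)
  expect_identical(s1, s2)
  s3 <- stratified_sample(pool, per_range = 100, seed = 8)
  expect_false(identical(s1, s3))
  # stratum of exactly per_range pulses is taken whole
  s4 <- stratified_sample(pool, per_range = 150, seed = 7)
  expect_equal(nrow(s4), 1200L)
  short <- pool[pool$subject_id == "A" & pool$activity_range == 0, ]
  expect_warning(s5 <- stratified_sample(short, per_range = 200, seed = 7),
                 "taking all")
  expect_equal(nrow(s5), 150L)
})
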
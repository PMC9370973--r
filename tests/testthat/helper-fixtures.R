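# Shared fixtures, built in code and memoized for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a clean (noise-free, still-wrist, full diastolic retention) configuration:
# every beat is Excellent by construction
clean_config <- function(duration_s = 60, hr = 60) {
  synth_config(n_subjects = 1, duration_s = max(120, duration_s),
               hr_mean = hr, hr_sd = 0, hr_jitter = 0,
               sys_amp_sd = 0,
               level_noise_sd = c(0, 0, 0, 0), noise_jitter_sd = 0,
               level_acc_amp = c(0, 0, 0, 0), acc_noise_sd = 1e-4,
               dia_retain_prob = 1)
}

# small default-parameter corpus shared by the SQI separation property and the
# end-to-end acceptance checks
small_corpus <- function() memo("small_corpus", {
  synth_cohort(synth_config(n_subjects = 8, duration_s = 480), seed = 3)
})

small_dataset <- function() memo("small_dataset", {
  build_quality_dataset(small_corpus(), per_range = 40, seed = 3)
})

# random pulse-like sequence for property tests
random_pulse <- function(n = 60) cumsum(stats::rnorm(n)) + sin(seq(0, 2 * pi, length.out = n))
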
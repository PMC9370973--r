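# Internal helpers: conditions, small numerics, deterministic seed substreams.

pq_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ppgqc_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_format     <- function(msg, ...) pq_error("ppgqc_format_error", msg, ...)
stop_integrity  <- function(msg, ...) pq_error("ppgqc_integrity_error", msg, ...)
stop_parameter  <- function(msg, ...) pq_error("ppgqc_parameter_error", msg, ...)
stop_degenerate <- function(msg, ...) pq_error("ppgqc_degenerate_pulse_error", msg, ...)
stop_task       <- function(msg, ...) pq_error("ppgqc_task_error", msg, ...)
stop_transform  <- function(msg, ...) pq_error("ppgqc_transform_error", msg, ...)
stop_config     <- function(msg, ...) pq_error("ppgqc_config_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic seed substream
#'
#' Combines a master seed with an integer key (e.g. a subject index) into a
#' new seed below 2^31, so that per-subject random streams are reproducible
#' and independent of processing order.
#'
#' @param seed master integer seed.
#' @param key non-negative integer key.
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(seed, key) {
  s <- abs(as.numeric(seed)) %% 1000003
  as.integer((s * 1009 + as.numeric(key) * 7919 + 12347) %% 2147483647)
}

# centered moving average, same length as input (edges use shrinking windows)
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  n <- length(x)
  if (n == 0L) return(numeric(0))
  cs <- cumsum(c(0, x))
  half <- width %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# linear resampling of a sequence onto n_out equally spaced points spanning
# the same index range
resample_to_length <- function(x, n_out) {
  n <- length(x)
  if (n < 2L) stop_integrity("cannot resample a sequence of fewer than 2 samples")
  if (n_out == n) return(x)
  stats::approx(x = seq_len(n), y = x, n = n_out)$y
}

# population moments
pop_var  <- function(x) mean((x - mean(x))^2)
pop_sd   <- function(x) sqrt(pop_var(x))
moment_skewness <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}
moment_kurtosis <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2
}
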
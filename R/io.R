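# Reading and writing recordings, pulse/label/feature tables, model
# artifacts, and the flat key: value config format used by the CLI.

#' Construct a PPG + accelerometer recording
#'
#' @param subject_id subject identifier.
#' @param ppg numeric vector of PPG samples (arbitrary units).
#' @param fs_ppg PPG sampling rate (Hz).
#' @param acc_x,acc_y,acc_z accelerometer channels in g units.
#' @param fs_acc accelerometer sampling rate (Hz).
#' @param acc_scale counts-per-g factor the raw channels were divided by
#'   (recorded for provenance; channels are stored in g).
#' @param start_time recording start, seconds since epoch.
#' @return an object of class `ppg_recording`.
#' @export
new_recording <- function(subject_id, ppg, fs_ppg, acc_x, acc_y, acc_z,
                          fs_acc, acc_scale = 1, start_time = 0) {
  if (length(ppg) == 0L) stop_integrity("PPG stream is empty")
  if (fs_ppg <= 0 || fs_acc <= 0) stop_integrity("sampling rates must be positive")
  if (length(acc_x) != length(acc_y) || length(acc_y) != length(acc_z))
    stop_integrity("accelerometer channels have mismatched lengths (%d/%d/%d)",
                   length(acc_x), length(acc_y), length(acc_z))
  structure(list(
    subject_id = as.character(subject_id),
    ppg = as.numeric(ppg), fs_ppg = fs_ppg,
    acc_x = as.numeric(acc_x), acc_y = as.numeric(acc_y),
    acc_z = as.numeric(acc_z), fs_acc = fs_acc,
    acc_scale = acc_scale, start_time = start_time
  ), class = "ppg_recording")
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf("<ppg_recording> subject %s: PPG %d samples @ %g Hz (%.1f s), ACC %d samples @ %g Hz\n",
              x$subject_id, length(x$ppg), x$fs_ppg, length(x$ppg) / x$fs_ppg,
              length(x$acc_x), x$fs_acc))
  invisible(x)
}

#' Read a PPG + accelerometer recording from CSV files
#'
#' Two on-disk dialects are supported:
#' \describe{
#'   \item{`e4`}{wristband-style export: first row is the start timestamp
#'     (seconds since epoch), second row the sampling rate, remaining rows the
#'     samples. The ACC file carries three comma-separated columns and its raw
#'     counts are converted to g with `acc_scale` (64 counts/g, the 8-bit
#'     +/-2 g convention).}
#'   \item{`generic`}{vendor-neutral: header `time_s,value` (PPG) or
#'     `time_s,x,y,z` (ACC, already in g); sampling rates are inferred from
#'     the median sample spacing.}
#' }
#'
#' @param ppg_path,acc_path paths to the PPG and ACC CSV files.
#' @param dialect `"e4"` or `"generic"`.
#' @param subject_id subject identifier to attach.
#' @param acc_scale counts-per-g conversion for the `e4` dialect.
#' @return a `ppg_recording`.
#' @export
read_recording <- function(ppg_path, acc_path, dialect = c("e4", "generic"),
                           subject_id = "S1", acc_scale = 64) {
  dialect <- match.arg(dialect)
  for (p in c(ppg_path, acc_path))
    if (!file.exists(p)) stop_format("file not found: %s", p)
  if (dialect == "e4") {
    ppg_raw <- read_e4_file(ppg_path, n_col = 1L)
    acc_raw <- read_e4_file(acc_path, n_col = 3L)
    new_recording(subject_id,
                  ppg = ppg_raw$data[, 1L], fs_ppg = ppg_raw$rate,
                  acc_x = acc_raw$data[, 1L] / acc_scale,
                  acc_y = acc_raw$data[, 2L] / acc_scale,
                  acc_z = acc_raw$data[, 3L] / acc_scale,
                  fs_acc = acc_raw$rate, acc_scale = acc_scale,
                  start_time = ppg_raw$start)
  } else {
    ppg <- utils::read.csv(ppg_path)
    acc <- utils::read.csv(acc_path)
    if (!identical(names(ppg), c("time_s", "value")))
      stop_format("generic PPG header must be 'time_s,value' (line 1 of %s)", ppg_path)
    if (!identical(names(acc), c("time_s", "x", "y", "z")))
      stop_format("generic ACC header must be 'time_s,x,y,z' (line 1 of %s)", acc_path)
    if (nrow(ppg) == 0L) stop_integrity("PPG stream is empty")
    # snap near-integer rates (guards against timestamp rounding in the file)
    snap <- function(fs) if (abs(fs - round(fs)) < 0.01) round(fs) else fs
    fs_ppg <- snap(1 / stats::median(diff(ppg$time_s)))
    fs_acc <- snap(1 / stats::median(diff(acc$time_s)))
    new_recording(subject_id, ppg = ppg$value, fs_ppg = fs_ppg,
                  acc_x = acc$x, acc_y = acc$y, acc_z = acc$z,
                  fs_acc = fs_acc, acc_scale = 1,
                  start_time = ppg$time_s[1L])
  }
}

read_e4_file <- function(path, n_col) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop_format("%s: expected timestamp, rate and samples", path)
  parse_row <- function(line, lineno) {
    v <- suppressWarnings(as.numeric(strsplit(line, ",", fixed = TRUE)[[1L]]))
    if (anyNA(v)) stop_format("%s: malformed numeric row at line %d", path, lineno)
    v
  }
  start <- parse_row(lines[1L], 1L)[1L]
  rate <- parse_row(lines[2L], 2L)[1L]
  rows <- lapply(seq.int(3L, length(lines)), function(i) {
    v <- parse_row(lines[i], i)
    if (length(v) != n_col)
      stop_format("%s: expected %d column(s) at line %d, found %d", path, n_col, i, length(v))
    v
  })
  list(start = start, rate = rate, data = do.call(rbind, rows))
}

#' Write a recording to CSV files
#'
#' Inverse of [read_recording()], in either dialect.
#'
#' @inheritParams read_recording
#' @param rec a `ppg_recording`.
#' @export
write_recording <- function(rec, ppg_path, acc_path, dialect = c("e4", "generic")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rec, "ppg_recording"))
  if (dialect == "e4") {
    writeLines(c(format(rec$start_time), format(rec$fs_ppg),
                 format(rec$ppg, trim = TRUE, digits = 15)), ppg_path)
    counts <- cbind(rec$acc_x, rec$acc_y, rec$acc_z) * rec$acc_scale
    hdr <- c(paste(rep(format(rec$start_time), 3L), collapse = ","),
             paste(rep(format(rec$fs_acc), 3L), collapse = ","))
    body <- apply(counts, 1L, function(r)
      paste(format(r, trim = TRUE, digits = 15), collapse = ","))
    writeLines(c(hdr, body), acc_path)
  } else {
    t_ppg <- sprintf("%.6f", rec$start_time + (seq_along(rec$ppg) - 1) / rec$fs_ppg)
    utils::write.csv(data.frame(time_s = t_ppg, value = rec$ppg),
                     ppg_path, row.names = FALSE, quote = FALSE)
    t_acc <- sprintf("%.6f", rec$start_time + (seq_along(rec$acc_x) - 1) / rec$fs_acc)
    utils::write.csv(data.frame(time_s = t_acc, x = rec$acc_x,
                                y = rec$acc_y, z = rec$acc_z),
                     acc_path, row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}

pulse_table_cols <- c("subject_id", "pulse_index", "foot_sample", "peak_sample",
                      "next_foot_sample", "start_time_s", "activity_index",
                      "activity_range")

validate_pulse_table <- function(pt) {
  missing <- setdiff(pulse_table_cols, names(pt))
  if (length(missing))
    stop_integrity("pulse table missing column(s): %s", paste(missing, collapse = ", "))
  if (nrow(pt) == 0L) return(invisible(pt))
  bad <- !(pt$foot_sample < pt$peak_sample & pt$peak_sample < pt$next_foot_sample)
  if (any(bad))
    stop_integrity("pulse table row %d violates foot < peak < next_foot", which(bad)[1L])
  ord <- order(pt$subject_id, pt$foot_sample)
  if (!identical(ord, seq_len(nrow(pt))))
    stop_integrity("pulse table rows not sorted by (subject_id, foot_sample)")
  ar <- pt$activity_range
  if (any(!is.na(ar) & !(ar %in% 0:3)))
    stop_integrity("activity_range outside {0,1,2,3}")
  invisible(pt)
}

#' Write / read a pulse table
#'
#' Plain CSV with one row per segmented pulse. Reading validates the table
#' invariants (window ordering, sortedness, activity range domain); writing a
#' table that violates them fails the same way.
#'
#' @param pt pulse table `data.frame` (see [detect_pulses()] /
#'   [segment_recording()]).
#' @param path file path.
#' @return `read_pulse_table()` returns the validated `data.frame`.
#' @export
write_pulse_table <- function(pt, path) {
  validate_pulse_table(pt)
  utils::write.csv(pt[, pulse_table_cols, drop = FALSE], path, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_pulse_table
#' @export
read_pulse_table <- function(path) {
  pt <- utils::read.csv(path, colClasses = c(subject_id = "character"))
  pt$activity_range <- as.integer(pt$activity_range)
  validate_pulse_table(pt)
  pt
}

#' Write / read a per-pulse label table
#'
#' CSV columns: `subject_id`, `pulse_index`, one `rater_<i>` column per rater
#' and `consensus`. Labels must be one of B, F, E.
#'
#' @param labels label `data.frame`.
#' @param path file path.
#' @export
write_label_table <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_label_table
#' @export
read_label_table <- function(path) {
  lab <- utils::read.csv(path, colClasses = c(subject_id = "character"))
  lab_cols <- grep("^rater_|^consensus$|^truth$", names(lab), value = TRUE)
  for (cl in lab_cols)
    if (any(!lab[[cl]] %in% c("B", "F", "E")))
      stop_integrity("column %s contains labels outside {B,F,E}", cl)
  lab
}

#' Write / read a per-pulse feature table
#'
#' One row per pulse: the pulse key (`subject_id`, `pulse_index`), the 19
#' signal-quality indices, plus any label/range columns present.
#'
#' @param features feature `data.frame`.
#' @param path file path.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, colClasses = c(subject_id = "character"))
}

#' Save / load a trained quality model artifact
#'
#' The artifact bundles family, hyperparameters, transform parameters, the
#' feature list, the fitted state and a format-version field.
#'
#' @param model a `quality_model` (see [train_quality_model()]).
#' @param path file path (binary artifact, written at run time).
#' @export
save_quality_model <- function(model, path) {
  stopifnot(inherits(model, "quality_model"))
  bundle <- list(format_version = 1L, model = model)
  saveRDS(bundle, path)
  invisible(NULL)
}

#' @rdname save_quality_model
#' @export
load_quality_model <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$format_version, 1L))
    stop_format("unsupported model artifact version: %s",
                format(bundle$format_version))
  bundle$model
}

#' Read a flat `key: value` config file
#'
#' Blank lines and lines starting with `#` are ignored. Values are parsed as
#' numeric where possible, `true`/`false` as logical, everything else kept as
#' a string.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: %s", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([^:]+):(.*)$", lines[i]))[[1L]]
    if (length(m) != 3L) stop_format("config line not 'key: value': %s", lines[i])
    key <- trimws(m[2L]); val <- trimws(m[3L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <-
      if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}
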
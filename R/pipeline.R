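# End-to-end orchestration: per-recording processing, cohort-level dataset
# assembly (segmentation -> activity ranges -> stratified sample -> labels ->
# SQIs), and the classification study harness.

#' Process one recording through segmentation and activity profiling
#'
#' @param rec a `ppg_recording`.
#' @param zero_phase use zero-phase filtering throughout.
#' @return list with `pulses` (pulse table with `activity_index` filled),
#'   `ppg_filtered`, `profile` (an `activity_profile`).
#' @export
process_recording <- function(rec, zero_phase = FALSE) {
  seg <- segment_recording(rec, zero_phase = zero_phase)
  prof <- activity_profile(rec, fs_out = rec$fs_ppg, zero_phase = zero_phase)
  pulses <- assign_pulse_ar(seg$pulses, prof, boundaries = NULL, fs = rec$fs_ppg)
  list(pulses = pulses, ppg_filtered = seg$ppg_filtered, profile = prof)
}

#' Ground-truth label for each detected pulse
#'
#' A detected pulse inherits the label of the simulated beat whose systolic
#' peak falls inside the pulse's half-open window; pulses containing no beat
#' peak or more than one are unusable by construction and labelled B.
#'
#' @param pulses detected pulse table.
#' @param beats ground-truth beat table (from [synth_recording()]).
#' @return character vector of B/F/E labels, one per pulse.
#' @export
label_pulses_from_beats <- function(pulses, beats) {
  vapply(seq_len(nrow(pulses)), function(i) {
    hit <- which(beats$peak_sample >= pulses$foot_sample[i] &
                   beats$peak_sample < pulses$next_foot_sample[i])
    if (length(hit) == 1L) beats$label[hit] else "B"
  }, character(1))
}

#' Beat-recovery statistics of the detector against ground truth
#'
#' Scores detected peaks against simulated beats, restricted to complete
#' interior beats (those preceded and followed by another beat, so a full
#' foot-to-foot window exists around them). A beat is recovered when a
#' detected peak lies within `tol` samples of its simulated peak.
#'
#' @param pulses detected pulse table.
#' @param beats ground-truth beat table.
#' @param tol matching tolerance in samples.
#' @return list with `recovery` (fraction), `max_err`, `mean_err` (samples,
#'   over recovered beats), `n_interior`.
#' @export
beat_recovery <- function(pulses, beats, tol = 3) {
  interior <- beats[seq_len(nrow(beats)) > 1L & seq_len(nrow(beats)) < nrow(beats), ]
  if (nrow(interior) == 0L || nrow(pulses) == 0L)
    return(list(recovery = 0, max_err = NA_real_, mean_err = NA_real_,
                n_interior = nrow(interior)))
  err <- vapply(interior$peak_sample, function(p)
    min(abs(pulses$peak_sample - p)), numeric(1))
  hit <- err <= tol
  list(recovery = mean(hit),
       max_err = if (any(hit)) max(err[hit]) else NA_real_,
       mean_err = if (any(hit)) mean(err[hit]) else NA_real_,
       n_interior = nrow(interior))
}

#' Assemble the labelled, stratified quality dataset from a cohort
#'
#' Runs the full front end of the pipeline: segments every recording,
#' computes activity profiles, pools the activity-index values to define the
#' quartile activity ranges, draws the stratified pulse sample (`per_range`
#' pulses per range per recording), attaches ground-truth labels and
#' simulated rater votes with their majority-vote consensus, and computes the
#' 19 signal quality indices for every sampled pulse.
#'
#' @param cohort a `synth_cohort`.
#' @param per_range pulses sampled per activity range per recording.
#' @param seed integer seed (sampling and rater substreams derive from it).
#' @param zero_phase use zero-phase filtering.
#' @return list with `features` (one row per sampled pulse: pulse key,
#'   activity columns, `truth`, `rater_1..3`, `consensus`, 19 SQI columns),
#'   `boundaries` (activity-range quartiles), `aind` (pooled values) and
#'   `n_detected` (pulses detected per subject).
#' @export
build_quality_dataset <- function(cohort, per_range = 100, seed = 1,
                                  zero_phase = FALSE) {
  stopifnot(inherits(cohort, "synth_cohort"))
  procs <- lapply(cohort$recordings, process_recording, zero_phase = zero_phase)
  aind <- unlist(lapply(procs, function(p) p$profile$a_index))
  boundaries <- define_activity_ranges(aind)

  pulses_all <- do.call(rbind, lapply(procs, function(p) {
    p$pulses$activity_range <- assign_activity_range(p$pulses$activity_index,
                                                     boundaries)
    p$pulses
  }))
  sampled <- stratified_sample(pulses_all, per_range = per_range, seed = seed)

  # per-subject: truth labels and SQIs for the sampled pulses
  feats <- lapply(seq_along(cohort$recordings), function(i) {
    sid <- cohort$subjects[i]
    p <- procs[[i]]
    sel <- sampled[sampled$subject_id == sid, , drop = FALSE]
    if (nrow(sel) == 0L) return(NULL)
    idx <- match(sel$pulse_index, p$pulses$pulse_index)
    sq <- compute_sqi_table(p$ppg_filtered, p$pulses,
                            acc_mag = p$profile$acc_mag,
                            fs = cohort$recordings[[i]]$fs_ppg, subset = idx)
    truth <- label_pulses_from_beats(sel, cohort$beats[[i]])
    cbind(sel, truth = truth, sq[idx, , drop = FALSE])
  })
  features <- do.call(rbind, feats)
  rownames(features) <- NULL

  votes <- synth_rater_votes(features$truth, cohort$config$rater_confusion,
                             seed = seed)
  features <- cbind(features[, setdiff(names(features), sqi_names)], votes,
                    features[, sqi_names])
  features <- consensus_labels(features)
  # degenerate pulses produce NA SQI rows; drop them here
  ok <- stats::complete.cases(features[, sqi_names])
  features <- features[ok, , drop = FALSE]
  list(features = features, boundaries = boundaries, aind = aind,
       n_detected = vapply(procs, function(p) nrow(p$pulses), integer(1)))
}

#' Condition features and build one task's train/test matrices
#'
#' Maps consensus labels to the task outcome (rows outside the task are
#' dropped), splits by subject, and applies the Box-Cox + z-score
#' conditioning. By default the conditioning is fitted separately on the
#' training and test partitions; `boxcox_from_train = TRUE` applies the
#' training parameters to the test partition instead (the leakage-free
#' variant). Features that are constant within a partition cannot be Box-Cox
#' transformed and are dropped from both partitions with a warning.
#'
#' @param features dataset from [build_quality_dataset()].
#' @param task a `task_spec`.
#' @param split subject split from [split_subjectwise()].
#' @param boxcox_from_train apply training transform parameters to test data.
#' @param label_col column holding the B/F/E labels to learn from.
#' @return list with `train_x`, `train_y`, `test_x`, `test_y`, `params`.
#' @export
prepare_task_data <- function(features, task, split,
                              boxcox_from_train = FALSE,
                              label_col = "consensus") {
  y_all <- task_outcome(task, features[[label_col]])
  keep <- !is.na(y_all)
  dat <- features[keep, , drop = FALSE]
  y_all <- y_all[keep]
  in_train <- dat$subject_id %in% split$train
  in_test <- dat$subject_id %in% split$test
  x_train <- as.matrix(dat[in_train, sqi_names, drop = FALSE])
  x_test <- as.matrix(dat[in_test, sqi_names, drop = FALSE])

  usable <- vapply(sqi_names, function(f)
    length(unique(x_train[, f])) > 1L && length(unique(x_test[, f])) > 1L,
    logical(1))
  if (!all(usable)) {
    warning("dropping constant feature(s): ",
            paste(sqi_names[!usable], collapse = ", "))
    x_train <- x_train[, usable, drop = FALSE]
    x_test <- x_test[, usable, drop = FALSE]
  }
  tr <- boxcox_zscore(x_train)
  te <- if (boxcox_from_train) list(x = apply_boxcox_zscore(x_test, tr$params),
                                    params = tr$params)
        else boxcox_zscore(x_test)
  list(train_x = tr$x, train_y = y_all[in_train],
       test_x = te$x, test_y = y_all[in_test],
       params = tr$params)
}

#' Run the classification study on an assembled dataset
#'
#' For each requested task: optional NCA feature selection (lambda tuning,
#' stability voting) on the training partition, then training and evaluation
#' of the requested model families on the chosen feature set, plus the two
#' literature baselines (similarity threshold, skewness SVM).
#'
#' @param features dataset from [build_quality_dataset()].
#' @param tasks task names to run.
#' @param families model families to train.
#' @param feature_set `"all"` (19 SQIs) or `"stable"` (NCA stable set).
#' @param train_frac,seed subject split parameters.
#' @param cv_folds,opt_iters,search hyperparameter search budget.
#' @param nca_grid_length,nca_folds,nca_max_n,nca_runs NCA problem sizes:
#'   lambda grid size, tuning folds, training-pulse cap for the NCA fits, and
#'   stability runs.
#' @param train_cap optional cap on training pulses per task (uniform
#'   subsample) to bound the hyperparameter search cost.
#' @param boxcox_from_train see [prepare_task_data()].
#' @param baselines run the two literature comparators.
#' @return object of class `quality_study`: per task a list with `models`
#'   (named `quality_model` list), `metrics` (data.frame, one row per
#'   method), `selection` (an `nca_selection` or NULL), `split`.
#' @export
run_quality_study <- function(features, tasks = c("BQ", "HQ1", "HQ2"),
                              families = quality_families,
                              feature_set = c("all", "stable"),
                              train_frac = 0.7, seed = 1,
                              cv_folds = 10, opt_iters = 30,
                              search = "smbo",
                              nca_grid_length = 20, nca_folds = 10,
                              nca_max_n = 600, nca_runs = 10,
                              train_cap = Inf, boxcox_from_train = FALSE,
                              baselines = TRUE) {
  feature_set <- match.arg(feature_set)
  split <- split_subjectwise(unique(features$subject_id),
                             train_frac = train_frac, seed = seed)
  out <- list()
  for (tn in tasks) {
    task <- quality_task(tn)
    td <- prepare_task_data(features, task, split,
                            boxcox_from_train = boxcox_from_train)
    tr_x <- td$train_x; tr_y <- td$train_y
    if (is.finite(train_cap) && nrow(tr_x) > train_cap) {
      set.seed(derive_seed(seed, 300L + match(tn, tasks)))
      idx <- sample(nrow(tr_x), train_cap)
      tr_x <- tr_x[idx, , drop = FALSE]; tr_y <- tr_y[idx]
    }

    selection <- NULL
    feats_used <- colnames(tr_x)
    if (feature_set == "stable") {
      nca_x <- tr_x; nca_y <- tr_y
      if (nrow(nca_x) > nca_max_n) {
        set.seed(derive_seed(seed, 400L + match(tn, tasks)))
        idx <- sample(nrow(nca_x), nca_max_n)
        nca_x <- nca_x[idx, , drop = FALSE]; nca_y <- nca_y[idx]
      }
      tuned <- nca_tune_lambda(nca_x, nca_y,
                               grid = nca_lambda_grid(nrow(nca_x),
                                                      nca_grid_length),
                               folds = nca_folds, seed = seed)
      selection <- nca_stable_select(nca_x, nca_y, lambda = tuned$lambda,
                                     runs = nca_runs, seed = seed)
      selection$cv_loss <- tuned$cv_loss
      if (length(selection$stable_set)) feats_used <- selection$stable_set
    }

    models <- list()
    rows <- list()
    for (fam in families) {
      m <- train_quality_model(tr_x[, feats_used, drop = FALSE], tr_y,
                               family = fam, cv_folds = cv_folds,
                               opt_iters = opt_iters, seed = seed,
                               search = search, task = task)
      rep <- evaluate_model(m, td$test_x[, feats_used, drop = FALSE], td$test_y)
      models[[fam]] <- m
      rows[[fam]] <- data.frame(task = tn, method = fam,
                                as.data.frame(rep[1:8]))
    }
    if (baselines) {
      jang <- sigsim_threshold_baseline(
        tr_x[, "SigSim"], tr_y, td$test_x[, "SigSim"], td$test_y)
      rows$Jang <- data.frame(task = tn, method = "Jang",
                              as.data.frame(jang$metrics[1:8]))
      elg <- skewness_svm_baseline(tr_x, tr_y, td$test_x, td$test_y,
                                   cv_folds = cv_folds,
                                   opt_iters = opt_iters, seed = seed,
                                   search = search)
      rows$Elgendi <- data.frame(task = tn, method = "Elgendi",
                                 as.data.frame(elg$metrics[1:8]))
      models$Jang <- jang
      models$Elgendi <- elg$model
    }
    out[[tn]] <- list(task = task, models = models,
                      metrics = do.call(rbind, c(rows, make.row.names = FALSE)),
                      selection = selection, split = split,
                      data = td, features_used = feats_used)
  }
  structure(out, class = "quality_study")
}

#' @export
print.quality_study <- function(x, ...) {
  for (tn in names(x)) {
    cat(sprintf("== task %s (features: %s) ==\n", tn,
                paste(x[[tn]]$features_used, collapse = ", ")))
    print(x[[tn]]$metrics, digits = 4, row.names = FALSE)
  }
  invisible(x)
}
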
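# Patient-level data preparation, the iterative-retraining fitness, and
# prospective test evaluation.

prep_segment <- function(rec) {
  filtered <- filter_recording(rec)
  tensor <- extract_features(segment_recording(filtered))
  list(tensor = tensor, onsets = rec$onsets,
       duration_s = recording_duration(rec))
}

#' Prepare a patient dataset for fitness evaluation and testing
#'
#' Filters, segments and feature-extracts every training segment and the
#' continuous testing record, and sets up the hyper-feature column cache
#' shared by all subsequent evaluations. Accepts either the output of
#' [simulate_patient()] or a directory written by [generate_patient()]
#' (training segments are taken in chronological file order).
#'
#' @param x a [simulate_patient()] result or a dataset directory path.
#' @param sampling_rate expected sampling rate when reading from disk.
#' @return a `patient_data` object.
#' @export
prepare_patient <- function(x, sampling_rate = 256) {
  if (is.character(x)) {
    files <- list.files(x, pattern = "^train_[0-9]+\\.(edf|csv)$",
                        full.names = TRUE)
    files <- files[order(basename(files))]
    if (!length(files)) stop("no train_* segments found in ", x)
    test_file <- list.files(x, pattern = "^test\\.(edf|csv)$",
                            full.names = TRUE)
    if (length(test_file) != 1L) stop("expected one test record in ", x)
    train <- lapply(files, read_recording, sampling_rate = sampling_rate,
                    expected_rate = sampling_rate)
    test <- read_recording(test_file, sampling_rate = sampling_rate,
                           expected_rate = sampling_rate)
  } else {
    train <- lapply(x$train, function(s) s$recording)
    test <- x$test$recording
  }
  if (length(train) < 2L)
    stop("at least 2 training seizures are required")
  structure(list(train = lapply(train, prep_segment),
                 test = prep_segment(test),
                 electrodes = test$channel_labels,
                 cache = new.env(parent = emptyenv())),
            class = "patient_data")
}

#' Prepare a synthetic patient one segment at a time
#'
#' Streaming counterpart of `prepare_patient(simulate_patient(...))`: each
#' segment is generated, filtered and reduced to its feature tensor before
#' the next one is touched, so peak memory stays near one raw segment
#' (hours of multichannel EEG reduce to a few MB of features).
#'
#' @inheritParams simulate_patient
#' @return a `patient_data` object.
#' @export
prepare_synthetic_patient <- function(config, n_train_seizures,
                                      n_test_seizures, train_hours = 4,
                                      test_lead_in_s = 7200,
                                      test_gap_s = 7200,
                                      test_tail_s = 1800) {
  plan <- patient_plan(config, n_train_seizures, n_test_seizures,
                       train_hours, test_lead_in_s, test_gap_s, test_tail_s)
  one <- function(cfg) {
    seg <- prep_segment(generate_recording(cfg)$recording)
    gc(FALSE)
    seg
  }
  train <- lapply(plan$train, one)
  test <- one(plan$test)
  structure(list(train = train, test = test,
                 electrodes = config$channel_labels,
                 cache = new.env(parent = emptyenv())),
            class = "patient_data")
}

#' @export
print.patient_data <- function(x, ...) {
  cat("<patient_data>", length(x$train), "training segment(s),",
      length(x$test$onsets), "testing seizure(s)\n")
  invisible(x)
}

# lag-expanded series of one prepared segment under one phenotype
segment_design <- function(patient, seg, seg_id, phenotype) {
  add_lags(build_series(seg$tensor, phenotype, seg$onsets,
                        cache = patient$cache, segment_id = seg_id))
}

# pooled training rows (excluded rows removed) from a list of designs
pool_training <- function(designs) {
  X <- do.call(rbind, lapply(designs, function(d) d$X))
  labels <- unlist(lapply(designs, function(d) d$labels))
  keep <- labels != "excluded"
  list(X = X[keep, , drop = FALSE], labels = labels[keep])
}

#' Fitness of an individual by iterative retraining
#'
#' For each training seizure j = 2..k the classifier is retrained on
#' seizures 1..j-1 and evaluated on seizure j (no refractory period);
#' fitness is the mean composite performance over the k-1 evaluated
#' seizures. Deterministic given genotype and data. An individual whose
#' model cannot be fitted (e.g. degenerate columns) receives the sentinel
#' fitness -10 so the GA discards it.
#'
#' @param ind an `individual`.
#' @param patient a [prepare_patient()] object.
#' @param min_preictal minimum pre-ictal period in minutes.
#' @param sph_min seizure prediction horizon (minutes, default 10).
#' @param fp_threshold Firing Power alarm threshold.
#' @return scalar fitness (<= 1, sentinel -10 on failure).
#' @export
evaluate_fitness <- function(ind, patient, min_preictal, sph_min = 10,
                             fp_threshold = 0.70) {
  stopifnot(inherits(patient, "patient_data"))
  k <- length(patient$train)
  tryCatch({
    phen <- decode_individual(ind, min_preictal, sph_min)
    designs <- lapply(seq_len(k), function(j)
      segment_design(patient, patient$train[[j]], paste0("tr", j), phen))
    perf <- vapply(2:k, function(j) {
      tr <- pool_training(designs[seq_len(j - 1L)])
      model <- suppressWarnings(fit_classifier(tr$X, tr$labels))
      evaluate_seizure(designs[[j]], model, mode = "fitness",
                       fp_threshold = fp_threshold)$performance
    }, numeric(1))
    mean(perf)
  }, error = function(e) -10)
}

#' Prospective evaluation of an individual on the continuous test record
#'
#' Retrains the classifier on all training seizures, then evaluates the
#' testing stretch with the same pipeline as the fitness function plus an
#' SOP+SPH refractory period after each alarm (refractory time is also
#' excluded from the FPR/h denominator).
#'
#' @inheritParams evaluate_fitness
#' @return list with `metrics` (a `perf_metrics`), the fitted `model`, the
#'   decoded `phenotype` and the test `alarms`.
#' @export
evaluate_test <- function(ind, patient, min_preictal, sph_min = 10,
                          fp_threshold = 0.70) {
  stopifnot(inherits(patient, "patient_data"))
  phen <- decode_individual(ind, min_preictal, sph_min)
  k <- length(patient$train)
  designs <- lapply(seq_len(k), function(j)
    segment_design(patient, patient$train[[j]], paste0("tr", j), phen))
  tr <- pool_training(designs)
  model <- suppressWarnings(fit_classifier(tr$X, tr$labels))
  test_design <- segment_design(patient, patient$test, "test", phen)
  metrics <- evaluate_seizure(test_design, model, mode = "test",
                              fp_threshold = fp_threshold)
  list(metrics = metrics, model = model, phenotype = phen,
       alarms = metrics$alarms, onsets = patient$test$onsets,
       test_duration_s = patient$test$duration_s)
}

#' Write per-seizure results and alarms as CSV tables
#'
#' @param results list of `evaluate_test()` outputs (one per execution).
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_test_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(seq_along(results), function(i) {
    m <- results[[i]]$metrics
    data.frame(execution = i, s_s = m$s_s, s_p = m$s_p, t_f = m$t_f,
               fpr_h = m$fpr_h, performance = m$performance,
               per_seizure = paste(as.integer(m$per_seizure),
                                   collapse = ";"))
  }))
  res_path <- file.path(dir, "test_metrics.csv")
  utils::write.csv(rows, res_path, row.names = FALSE)
  alarms <- do.call(rbind, lapply(seq_along(results), function(i) {
    a <- results[[i]]$alarms
    if (!length(a$times)) return(NULL)
    phen <- results[[i]]$phenotype
    onsets <- results[[i]]$onsets
    flag <- vapply(a$times, function(t)
      any(t >= onsets - phen$pre_ictal_min * 60 &
            t < onsets - phen$sph_min * 60), logical(1))
    data.frame(execution = i, time_s = a$times,
               seizure_predicted_flag = flag)
  }))
  alarm_path <- file.path(dir, "alarms.csv")
  utils::write.csv(alarms %||% data.frame(execution = integer(0),
                                          time_s = numeric(0),
                                          seizure_predicted_flag = logical(0)),
                   alarm_path, row.names = FALSE)
  invisible(c(res_path, alarm_path))
}
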
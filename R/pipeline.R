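# End-to-end orchestration: synthetic data -> features -> evolution ->
# prospective testing -> surrogate validation -> phenotype study, with a
# reproducibility manifest.

#' Validate a run configuration
#'
#' @param min_preictal minimum pre-ictal period, minutes; must belong to
#'   `allowed_preictal` and exceed the SPH.
#' @param sph_min seizure prediction horizon, minutes (default 10).
#' @param fp_threshold Firing Power alarm threshold.
#' @param allowed_preictal admissible minimum pre-ictal periods.
#' @return invisibly TRUE; errors on an invalid combination.
#' @export
validate_run_config <- function(min_preictal, sph_min = 10,
                                fp_threshold = 0.70,
                                allowed_preictal = c(40, 50, 60)) {
  if (!min_preictal %in% allowed_preictal)
    stop("min_preictal must be one of ",
         paste(allowed_preictal, collapse = ", "), " minutes")
  if (sph_min >= min_preictal)
    stop("SPH (", sph_min, " min) must be smaller than the minimum ",
         "pre-ictal period (", min_preictal, " min)")
  if (fp_threshold <= 0 || fp_threshold >= 1)
    stop("fp_threshold must lie in (0, 1)")
  invisible(TRUE)
}

#' Run the complete pipeline on a synthetic patient
#'
#' Chains every stage with one seed: generate the patient (training
#' segments plus the continuous testing stretch), extract features, run the
#' GA executions, test each execution's best individual prospectively,
#' compare against the surrogate predictor, validate statistically and
#' produce the phenotype report. All artifacts plus a manifest (config,
#' seeds, package version) are written under `out_dir`.
#'
#' @param out_dir output directory for artifacts.
#' @param synth a [synth_config()] describing the patient.
#' @param n_train,n_test number of training / testing seizures.
#' @param min_preictal minimum pre-ictal period (minutes).
#' @param sph_min seizure prediction horizon (minutes).
#' @param fp_threshold Firing Power alarm threshold.
#' @param ga a [ga_config()].
#' @param n_surrogate surrogate repetitions per execution.
#' @param seed master seed driving every stage.
#' @param train_hours,test_lead_in_s,test_gap_s,test_tail_s data layout
#'   passed to [simulate_patient()].
#' @return list with `executions`, `tests`, `surrogates`, `validation`,
#'   `phenotype`, `paths`.
#' @export
run_pipeline <- function(out_dir,
                         synth = synth_config(seed = 1L),
                         n_train = 3L, n_test = 2L,
                         min_preictal = 40, sph_min = 10,
                         fp_threshold = 0.70,
                         ga = ga_config(),
                         n_surrogate = 30L,
                         seed = 1L,
                         train_hours = 4,
                         test_lead_in_s = 7200, test_gap_s = 7200,
                         test_tail_s = 1800) {
  validate_run_config(min_preictal, sph_min, fp_threshold)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  synth$seed <- synth$seed %||% seed
  patient <- prepare_synthetic_patient(synth, n_train, n_test,
                                       train_hours = train_hours,
                                       test_lead_in_s = test_lead_in_s,
                                       test_gap_s = test_gap_s,
                                       test_tail_s = test_tail_s)
  domains <- gene_domains(electrodes = patient$electrodes)
  executions <- run_patient(patient, domains, ga, min_preictal,
                            seed = seed,
                            out_dir = file.path(out_dir, "executions"))
  tests <- lapply(executions, function(ex)
    evaluate_test(ex$best, patient, min_preictal, sph_min, fp_threshold))
  surrogates <- lapply(seq_along(tests), function(i)
    surrogate_sensitivity(tests[[i]]$alarms$times,
                          patient$test$onsets,
                          patient$test$duration_s,
                          tests[[i]]$phenotype$pre_ictal_min,
                          sph_min = sph_min, n_reps = n_surrogate,
                          seed = seed + 10000L + i))
  real_sens <- lapply(tests, function(t)
    as.numeric(t$metrics$per_seizure))
  validation <- validate_patient(real_sens, surrogates)
  phen_report <- phenotype_report(lapply(executions, `[[`, "best"),
                                  lapply(tests, `[[`, "model"),
                                  domains)
  write_test_results(tests, out_dir)
  write_validation_report(validation, file.path(out_dir, "validation.json"))
  write_phenotype_report(phen_report, out_dir)
  manifest <- list(
    package_version = as.character(utils::packageVersion("evoseize")),
    r_version = as.character(getRversion()),
    seed = seed,
    min_preictal = min_preictal, sph_min = sph_min,
    fp_threshold = fp_threshold,
    n_train = n_train, n_test = n_test,
    synth = synth[setdiff(names(synth), "channel_labels")],
    ga = unclass(ga),
    n_surrogate = n_surrogate)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest$config_hash <- unname(tools::md5sum(manifest_path))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  list(executions = executions, tests = tests, surrogates = surrogates,
       validation = validation, phenotype = phen_report,
       paths = list(dir = out_dir, manifest = manifest_path))
}
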
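#' Pipeline configuration
#'
#' Settings for the end-to-end simulated-cohort run: simulate each patient's
#' waveforms, extract per-beat features, train the four regressors per
#' target, select the best algorithm by mean validation RMSE, evaluate the
#' pooled test-set errors against the AAMI/BHS standards and aggregate the
#' random-forest feature importances.
#'
#' Patients alternate arrhythmia profiles in roughly the 15:20
#' ventricular:supraventricular mix of the study population: the first
#' ~43% of patients are PVC-dominant, the rest run-dominant.
#'
#' @param n_patients cohort size.
#' @param sim a [sim_config()] template (per-patient seed and arrhythmia mix
#'   are derived from it).
#' @param split a [split_spec()].
#' @param algorithms algorithms to train.
#' @param targets `"sbp"`, `"dbp"` or both.
#' @param seed root seed; all per-patient and per-fit seeds derive from it.
#' @param out_dir output directory (`NULL` for no files).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_patients = 10,
                            sim = sim_config(duration = 240,
                                             artifact_fraction = 0.05),
                            split = split_spec(),
                            algorithms = algorithm_order,
                            targets = c("sbp", "dbp"),
                            seed = 1L, out_dir = NULL) {
  structure(list(n_patients = n_patients, sim = sim, split = split,
                 algorithms = match.arg(algorithms, algorithm_order,
                                        several.ok = TRUE),
                 targets = match.arg(targets, c("sbp", "dbp"),
                                     several.ok = TRUE),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

simulate_patient_features <- function(config, i) {
  cfg <- config$sim
  cfg$seed <- config$seed * 1000L + i
  n_vent <- round(0.43 * config$n_patients)
  if (i <= n_vent) {
    cfg$pvc_probability <- 0.15
    cfg$svt_run_probability <- 0.01
  } else {
    cfg$pvc_probability <- 0.02
    cfg$svt_run_probability <- 0.10
  }
  cfg$base_hr <- 60 + ((config$seed + i * 7) %% 5) * 7
  pid <- sprintf("sim%02d", i)
  sim <- simulate_record(cfg, patient_id = pid)
  labels <- data.frame(time_s = sim$truth$beat_time,
                       beat_type = sim$truth$beat_type)
  feats <- extract_beat_features(sim$record, beat_labels = labels)
  attr(feats, "patient_id") <- pid
  feats
}

#' Run the full estimation pipeline on a simulated cohort
#'
#' @param config a [pipeline_config()].
#' @param features optional list of pre-computed per-patient feature tables
#'   (bypasses simulation; used e.g. with [simulate_feature_cohort()]).
#' @return list with per-target results (`val_rmse` matrix, selected
#'   algorithm, pooled test metrics, `aami`, `bhs`, `bland_altman`,
#'   `by_beat_type`, per-patient metrics, `importance`) plus `features`
#'   and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), features = NULL) {
  if (is.null(features))
    features <- lapply(seq_len(config$n_patients), function(i)
      simulate_patient_features(config, i))
  n_pat <- length(features)
  pids <- vapply(seq_len(n_pat), function(i)
    attr(features[[i]], "patient_id") %||% sprintf("p%02d", i), character(1))

  results <- list()
  for (target in config$targets) {
    val_rmse <- matrix(NA_real_, n_pat, length(config$algorithms),
                       dimnames = list(pids, config$algorithms))
    models <- list()
    splits <- list()
    for (i in seq_len(n_pat)) {
      rows <- features[[i]]
      rows <- rows[rows$quality_pass, , drop = FALSE]
      sp <- split_patient(rows, config$split)
      splits[[i]] <- sp
      models[[i]] <- list()
      for (alg in config$algorithms) {
        m <- train_model(alg, sp$train, sp$val, target = target,
                         seed = config$seed + i, patient_id = pids[i])
        val_rmse[i, alg] <- m$val_rmse
        models[[i]][[alg]] <- m
      }
    }
    best <- select_best_algorithm(val_rmse)
    per_patient <- lapply(seq_len(n_pat), function(i) {
      sp <- splits[[i]]
      est <- stats::predict(models[[i]][[best]], sp$test)
      ref <- sp$test[[paste0("ref_", target)]]
      c(list(patient_id = pids[i]), error_metrics(est, ref))
    })
    pooled_est <- unlist(lapply(seq_len(n_pat), function(i)
      stats::predict(models[[i]][[best]], splits[[i]]$test)))
    pooled_ref <- unlist(lapply(splits, function(sp)
      sp$test[[paste0("ref_", target)]]))
    pooled_type <- unlist(lapply(splits, function(sp) sp$test$beat_type))
    pooled <- error_metrics(pooled_est, pooled_ref)
    imp <- if ("RFR" %in% config$algorithms)
      group_importance(lapply(models, `[[`, "RFR")) else NULL
    results[[target]] <- list(
      val_rmse = val_rmse,
      best_algorithm = best,
      per_patient = per_patient,
      per_patient_rmse_mean = mean(vapply(per_patient, `[[`,
                                          numeric(1), "rmse")),
      per_patient_rmse_sd = stats::sd(vapply(per_patient, `[[`,
                                             numeric(1), "rmse")),
      pooled = pooled,
      aami = aami_check(pooled$me, pooled$std, n_pat),
      bhs = bhs_grade(abs(pooled_est - pooled_ref)),
      bland_altman = bland_altman(pooled_est, pooled_ref),
      by_beat_type = evaluate_by_beat_type(pooled_est, pooled_ref,
                                           pooled_type),
      importance = imp)
  }

  manifest <- list(seed = config$seed, n_patients = n_pat,
                   algorithms = config$algorithms,
                   targets = config$targets,
                   split = unclass(config$split)[c("train", "val", "test",
                                                   "mode")],
                   r_version = as.character(getRversion()),
                   timestamp = format(Sys.time(), tz = "UTC"))
  out <- list(results = results, features = features, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_pat))
      write_feature_table(features[[i]],
                          file.path(config$out_dir,
                                    paste0("features_", pids[i], ".csv")))
    for (target in config$targets) {
      res <- results[[target]]
      utils::write.csv(res$val_rmse,
                       file.path(config$out_dir,
                                 paste0("val_rmse_", target, ".csv")))
      if (!is.null(res$importance))
        utils::write.csv(res$importance$table,
                         file.path(config$out_dir,
                                   paste0("importance_", target, ".csv")),
                         row.names = FALSE)
    }
    report <- lapply(results, function(res)
      list(best_algorithm = res$best_algorithm,
           per_patient_rmse_mean = res$per_patient_rmse_mean,
           per_patient_rmse_sd = res$per_patient_rmse_sd,
           pooled = res$pooled, aami = res$aami, bhs = res$bhs,
           bland_altman = res$bland_altman,
           by_beat_type = res$by_beat_type))
    jsonlite::write_json(list(report = report, manifest = manifest),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
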
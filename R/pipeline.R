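# End-to-end orchestration: simulate -> label -> windows -> features ->
# train -> evaluate -> alerts, plus the sensitivity-analysis suite.

#' Pipeline run configuration
#'
#' @param sim A [sim_config()].
#' @param scheme A [window_scheme()].
#' @param k_folds Cross-validation folds (default 10, patient-grouped).
#' @param grid Hyperparameter grid (default [default_grid()]).
#' @param use_constraints Apply the monotone constraint map (default TRUE).
#' @param feature_set `"all"` or `"selected"` (SHAP top-`k_features`).
#' @param k_features Features kept by SHAP selection (default 61).
#' @param label_criteria `"full"`, `"creatinine_only"` or `"uo_only"`.
#' @param pt Operating threshold; `NULL` (default) selects the
#'   F2-maximizing threshold on out-of-fold predictions.
#' @param boot_B Bootstrap replicates for evaluation CIs (default 2000).
#' @param seed Master seed (folds, booster, bootstrap).
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), scheme = window_scheme(),
                       k_folds = 10L, grid = default_grid(),
                       use_constraints = TRUE,
                       feature_set = c("all", "selected"),
                       k_features = 61L,
                       label_criteria = c("full", "creatinine_only", "uo_only"),
                       pt = NULL, boot_B = 2000L, seed = 1L) {
  feature_set <- match.arg(feature_set)
  label_criteria <- match.arg(label_criteria)
  structure(list(sim = sim, scheme = scheme, k_folds = as.integer(k_folds),
                 grid = grid, use_constraints = use_constraints,
                 feature_set = feature_set, k_features = as.integer(k_features),
                 label_criteria = label_criteria, pt = pt,
                 boot_B = as.integer(boot_B), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline on a synthetic (or supplied) cohort
#'
#' Stages: simulate (or accept a cohort), KDIGO labelling, exclusions and
#' rolling windows with patient-grouped folds, feature engineering with
#' encoding and screening, constrained boosting with grid search, Platt
#' recalibration and threshold selection on out-of-fold predictions,
#' window-level evaluation, and event-level alert analytics. Writes the
#' stage tables and a JSON manifest when `out_dir` is given.
#'
#' @param config A [run_config()].
#' @param cohort Optional prebuilt `aki_cohort` (skips simulation).
#' @param out_dir Optional output directory.
#' @return List with all stage outputs (see names) and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL, out_dir = NULL) {
  stages <- character()
  t_start <- Sys.time()

  if (is.null(cohort)) cohort <- simulate_cohort(config$sim)
  stages <- c(stages, "simulate")

  assessments <- assess_cohort(cohort, criteria = config$label_criteria)
  onsets <- aki_onsets(cohort, assessments)
  stages <- c(stages, "label")

  excl <- apply_exclusions(cohort, onsets, config$scheme)
  windows <- build_cohort_windows(excl$stays, onsets, config$scheme)
  if (!nrow(windows)) stopf("stage 'windows' produced no prediction windows")
  folds <- assign_folds(windows, config$k_folds, seed = config$seed)
  stages <- c(stages, "windows")

  X <- build_feature_matrix(cohort, windows)
  enc <- encode_categoricals(X)
  all_feats <- setdiff(names(enc$X),
                       c("window_id", "patient_id", "stay_id", "cutoff", "label"))
  scr <- screen_features(enc$X, all_feats, train_mask = rep(TRUE, nrow(enc$X)))
  feats <- scr$retained
  stages <- c(stages, "features")

  cons <- if (config$use_constraints) default_constraints(feats) else NULL
  bundle <- tune_and_train(enc$X, feats, enc$X$label, folds,
                           grid = config$grid, constraints = cons,
                           seed = config$seed)
  selection <- NULL
  if (config$feature_set == "selected" &&
      config$k_features < length(feats)) {
    selection <- shap_select(bundle, enc$X, enc$X$label, k = config$k_features)
    bundle <- selection$bundle
  }
  stages <- c(stages, "train")

  platt <- platt_fit(bundle$oof$raw, bundle$oof$label)
  bundle$platt <- platt
  recal <- platt_apply(bundle$oof$raw, platt)
  pt <- config$pt %||% choose_threshold(recal, bundle$oof$label, beta = 2)
  bundle$pt <- pt

  report <- metrics_report(recal, bundle$oof$label, bundle$oof$patient_id,
                           pt = pt, B = config$boot_B, seed = config$seed)
  calib <- calibration_suite(recal, bundle$oof$label)
  dca <- dca_curve(recal, bundle$oof$label)
  stages <- c(stages, "evaluate")

  alerts <- extract_alerts(windows, recal, pt, onsets, config$scheme)
  eval_onsets <- onsets[stay_id %in% excl$stays$stay_id]
  lead <- lead_time_detection(alerts, eval_onsets)
  burden <- burden_metrics(alerts, excl$stays, config$scheme)
  stages <- c(stages, "alerts")

  manifest <- list(
    package_version = as.character(utils::packageVersion("akiews")),
    seed = config$seed,
    stages = stages,
    n_patients = config$sim$n_patients,
    n_stays = nrow(cohort$stays),
    n_excluded = nrow(excl$log),
    n_windows = nrow(windows),
    prevalence = mean(windows$label),
    n_features = length(feats),
    pt = pt,
    platt = as.list(platt),
    cv_auc = bundle$cv_auc)

  out <- list(cohort = cohort, assessments = assessments, onsets = onsets,
              exclusions = excl, windows = windows, folds = folds,
              features = enc$X, feature_names = feats, screening = scr,
              selection = selection, bundle = bundle, recalibrated = recal,
              pt = pt, report = report, calibration = calib, dca = dca,
              alerts = alerts, lead_time = lead, burden = burden,
              manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    fwrite(onsets, file.path(out_dir, "onsets.csv"))
    fwrite(excl$log, file.path(out_dir, "exclusions.csv"))
    fwrite(windows, file.path(out_dir, "windows.csv"))
    fwrite(out$features, file.path(out_dir, "features.csv"))
    fwrite(report, file.path(out_dir, "metrics.csv"))
    fwrite(dca, file.path(out_dir, "dca.csv"))
    fwrite(alerts, file.path(out_dir, "alerts.csv"))
    fwrite(lead, file.path(out_dir, "lead_time.csv"))
    manifest$file_md5 <- as.list(tools::md5sum(
      list.files(out_dir, pattern = "\\.csv$", full.names = TRUE,
                 recursive = TRUE)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out$manifest <- manifest
  invisible(out)
}

#' Sensitivity-analysis suite
#'
#' Re-runs training/evaluation under prespecified contrasts against a base
#' run: monotone constraints on vs off, all features vs the SHAP-selected
#' subset, the full KDIGO label vs creatinine-only and urine-output-only
#' variants, and injected laboratory missingness. Each row reports AUC and
#' AUPRC with patient-clustered bootstrap CIs.
#'
#' @param config Base [run_config()].
#' @param base Optional precomputed [run_pipeline()] result for `config`.
#' @param missingness_fractions Extra fractions of lab rows to delete
#'   (default 0.5 and 0.9).
#' @param boot_B Bootstrap replicates for the CIs (default 200; the
#'   suite refits one model per contrast).
#' @return data.table `contrast`, `auc`, `auc_lo`, `auc_hi`, `auprc`,
#'   `n_windows`, `prevalence`, `note`.
#' @export
run_sensitivity_suite <- function(config = run_config(), base = NULL,
                                  missingness_fractions = c(0.5, 0.9),
                                  boot_B = 200L) {
  if (is.null(base)) base <- run_pipeline(config)
  cohort <- base$cohort

  eval_run <- function(run, contrast, note = NA_character_) {
    oof <- run$bundle$oof
    ci <- cluster_bootstrap(function(df) {
      tryCatch(rank_metrics(df$raw, df$label)$auc, error = function(e) NA_real_)
    }, oof, oof$patient_id, B = boot_B, seed = config$seed)
    rm_ <- rank_metrics(oof$raw, oof$label)
    data.table(contrast = contrast, auc = rm_$auc, auc_lo = ci$lower,
               auc_hi = ci$upper, auprc = rm_$auprc,
               n_windows = nrow(oof), prevalence = mean(oof$label),
               note = note)
  }

  rerun <- function(cfg, cohort_) {
    tryCatch(run_pipeline(cfg, cohort = cohort_), error = function(e) e)
  }
  rows <- list(eval_run(base, "base"))

  cfg <- config; cfg$use_constraints <- !config$use_constraints
  r <- rerun(cfg, cohort)
  rows <- c(rows, list(if (inherits(r, "error"))
    data.table(contrast = "constraints_toggled", auc = NA_real_,
               auc_lo = NA_real_, auc_hi = NA_real_, auprc = NA_real_,
               n_windows = 0L, prevalence = NA_real_,
               note = "not_computable")
    else eval_run(r, "constraints_toggled")))

  if (config$feature_set == "all") {
    cfg <- config; cfg$feature_set <- "selected"
    r <- rerun(cfg, cohort)
    if (!inherits(r, "error"))
      rows <- c(rows, list(eval_run(r, "selected_features")))
  }

  for (crit in setdiff(c("creatinine_only", "uo_only"), config$label_criteria)) {
    cfg <- config; cfg$label_criteria <- crit
    r <- rerun(cfg, cohort)
    rows <- c(rows, list(if (inherits(r, "error"))
      data.table(contrast = paste0("labels_", crit), auc = NA_real_,
                 auc_lo = NA_real_, auc_hi = NA_real_, auprc = NA_real_,
                 n_windows = 0L, prevalence = NA_real_,
                 note = "not_computable")
      else eval_run(r, paste0("labels_", crit))))
  }

  for (fr in missingness_fractions) {
    set.seed(config$seed + round(1000 * fr))
    thinned <- cohort
    keep <- runif(nrow(cohort$labs)) > fr
    thinned$labs <- cohort$labs[keep]
    r <- rerun(config, thinned)
    rows <- c(rows, list(if (inherits(r, "error"))
      data.table(contrast = sprintf("lab_missingness_%g", fr), auc = NA_real_,
                 auc_lo = NA_real_, auc_hi = NA_real_, auprc = NA_real_,
                 n_windows = 0L, prevalence = NA_real_,
                 note = "not_computable")
      else eval_run(r, sprintf("lab_missingness_%g", fr))))
  }
  rbindlist(rows)
}
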
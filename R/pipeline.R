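#' Assemble a validated pipeline run configuration
#'
#' Collects every tunable of the end-to-end run — cohort size, generator noise
#' levels, synergy threshold, window geometry, filter band, PCA rule, fold
#' count and seed — into one validated list that can be serialized alongside
#' the run's outputs for reproducibility.
#'
#' @param n_subjects Cohort size.
#' @param n_syn Ground-truth synergy count of the generator.
#' @param threshold Synergy-selection cumulative-variance threshold.
#' @param window_ms,overlap_ms Feature window geometry (ms).
#' @param filter_band Preprocessing/feature band (Hz).
#' @param pca_rule Feature-reduction rule.
#' @param n_folds Cross-validation folds.
#' @param seed Master seed.
#' @param noise_sd_kin,noise_sd_feat Generator noise levels.
#' @param protocol A `grasp_protocol`.
#' @param compute_maps Also compute the independency map (on the final fold's
#'   training subjects).
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_subjects = 10, n_syn = 6, threshold = 0.85,
                       window_ms = 500, overlap_ms = 375,
                       filter_band = c(0.1, 56), pca_rule = 0.9,
                       n_folds = 10, seed = 1,
                       noise_sd_kin = 6, noise_sd_feat = 0.05,
                       protocol = grasp_protocol(),
                       compute_maps = FALSE) {
  stopifnot(is_count(n_subjects, 2L), is_count(n_syn), is_count(n_folds),
            threshold > 0, threshold <= 1,
            length(filter_band) == 2, filter_band[1] < filter_band[2],
            inherits(protocol, "grasp_protocol"))
  structure(list(n_subjects = n_subjects, n_syn = n_syn,
                 threshold = threshold, window_ms = window_ms,
                 overlap_ms = overlap_ms, filter_band = filter_band,
                 pca_rule = pca_rule, n_folds = n_folds, seed = seed,
                 noise_sd_kin = noise_sd_kin, noise_sd_feat = noise_sd_feat,
                 protocol = protocol, compute_maps = compute_maps),
            class = "run_config")
}

#' Run the full synthesize-extract-decode-evaluate pipeline
#'
#' Generates a synthetic cohort from the configuration, extracts velocity and
#' feature matrices, runs shuffled cross-subject cross-validation, and
#' aggregates accuracy overall and by joint and grasp. With `out_dir` set, the
#' run's tables, per-fold metadata, a machine-readable `summary.json` and the
#' serialized configuration are written there. Rerunning with the same
#' configuration and seed reproduces all numeric outputs.
#'
#' @param config A `run_config`.
#' @param out_dir Optional output directory.
#' @return Invisibly, a list with `summary` (one-row tibble), `overall`,
#'   `by_joint`, `by_grasp`, `fold_table`, `cv`, `cohort` and (optionally)
#'   `maps`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  epoch_samples <- round(config$protocol$epoch_s * config$protocol$kin_rate)
  gt <- make_ground_truth(n_syn = config$n_syn,
                          epoch_samples = epoch_samples,
                          n_grasps = config$protocol$n_grasps,
                          seed = derive_seed(config$seed, 101L),
                          noise_sd_kin = config$noise_sd_kin,
                          noise_sd_feat = config$noise_sd_feat)
  cohort <- generate_cohort(gt, n_subjects = config$n_subjects,
                            protocol = config$protocol,
                            seed = derive_seed(config$seed, 202L))
  features <- cohort_features(cohort, band = config$filter_band,
                              window_ms = config$window_ms,
                              overlap_ms = config$overlap_ms)
  velocity <- cohort_velocity(cohort)
  cv <- cross_validate(cohort, n_folds = config$n_folds,
                       seed = derive_seed(config$seed, 303L),
                       threshold = config$threshold,
                       pca_rule = config$pca_rule,
                       band = config$filter_band,
                       features = features, velocity = velocity)
  overall <- aggregate_accuracy(cv, "overall")
  by_joint <- aggregate_accuracy(cv, "joint")
  by_grasp <- aggregate_accuracy(cv, "grasp")
  fold_table <- representative_fold_table(cv, fold = 1)
  summary <- dplyr::bind_cols(
    tibble(n_subjects = config$n_subjects, n_folds = config$n_folds,
           seed = config$seed),
    overall,
    tibble(mean_n_syn = mean(cv$folds$n_syn),
           mean_pca_components = mean(cv$folds$pca_components))
  )
  out <- list(summary = summary, overall = overall, by_joint = by_joint,
              by_grasp = by_grasp, fold_table = fold_table, cv = cv,
              cohort = cohort)
  if (isTRUE(config$compute_maps)) {
    last <- as.integer(strsplit(cv$folds$train_subjects[config$n_folds],
                                ",")[[1]])
    tr_rows <- which(features$trial_index$subject %in% last)
    vm_tr <- vm_subset(velocity, tr_rows)
    syn <- select_synergies(synergy_svd(vm_tr), config$threshold)
    W <- project_weights(vm_tr, syn)
    out$maps <- independency_density(fm_subset(features, tr_rows), W,
                                     montage = cohort$subjects[[1]]$eeg$montage)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(cv$results, file.path(out_dir, "cv_results.csv"))
    readr::write_csv(cv$folds, file.path(out_dir, "fold_metadata.csv"))
    readr::write_csv(overall, file.path(out_dir, "accuracy_overall.csv"))
    readr::write_csv(by_joint, file.path(out_dir, "accuracy_by_joint.csv"))
    readr::write_csv(by_grasp, file.path(out_dir, "accuracy_by_grasp.csv"))
    readr::write_csv(fold_table, file.path(out_dir, "fold1_task_by_subject.csv"))
    if (!is.null(out$maps)) {
      readr::write_csv(out$maps, file.path(out_dir, "independency_map.csv"))
    }
    jsonlite::write_json(
      list(summary = as.list(summary),
           config = config_to_list(config)),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$protocol <- unclass(out$protocol)
  out
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  proto <- do.call(grasp_protocol, raw$protocol)
  raw$protocol <- proto
  raw$filter_band <- as.numeric(raw$filter_band)
  do.call(run_config, raw)
}
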
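#' Pearson correlation between recorded and decoded traces
#'
#' Standard sample correlation. A constant recorded (or decoded) series leaves
#' the correlation undefined; that raises an error of class
#' `synergydecoder_constant_series`, which the cross-validation loop catches by
#' flagging the trial instead of scoring it.
#'
#' @param recorded,decoded Equal-length numeric vectors (length >= 3).
#' @return The correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_rho(1:5, 5:1)  # -1
#' @export
pearson_rho <- function(recorded, decoded) {
  if (length(recorded) != length(decoded)) {
    abort("series must have equal length")
  }
  if (length(recorded) < 3) abort("series must have at least 3 samples")
  if (sd(recorded) == 0 || sd(decoded) == 0) {
    abort("correlation undefined for a constant series",
          class = "synergydecoder_constant_series")
  }
  cor(recorded, decoded)
}

#' Decoding error from a correlation coefficient
#'
#' Defined as `1 - |rho|`, so both perfect correlation and perfect
#' anti-correlation count as zero error.
#'
#' @param rho Correlation coefficient(s) in `[-1, 1]` (NA allowed).
#' @return `1 - |rho|`, in `[0, 1]`.
#' @export
decoding_error <- function(rho) {
  bad <- !is.na(rho) & (rho < -1 - 1e-12 | rho > 1 + 1e-12)
  if (any(bad)) abort("rho must lie in [-1, 1]")
  1 - abs(rho)
}

#' Aggregate decoding accuracy
#'
#' Grouped mean and standard deviation of the per-trial-per-joint Pearson
#' correlations (reported in percent, the Table-2 convention) and of the
#' decoding error `1 - |rho|`. Flagged trials (undefined correlation) are
#' excluded. `by` may be one of the convenience groupings or any character
#' vector of column names in the results.
#'
#' @param results A `synergy_cv` object or its `results` tibble.
#' @param by `"overall"`, `"joint"`, `"grasp"`, `"subject"`,
#'   `"task_subject"`, or a character vector of grouping columns.
#' @return A tibble with grouping columns plus `n`, `accuracy_mean`,
#'   `accuracy_sd` (percent) and `error_mean`, `error_sd`.
#' @export
aggregate_accuracy <- function(results, by = "overall") {
  if (inherits(results, "synergy_cv")) results <- results$results
  results <- as_tibble(results)
  if (!"flagged" %in% names(results)) results$flagged <- FALSE
  results <- dplyr::filter(results, !.data$flagged, !is.na(.data$rho))
  groups <- switch(by[1],
    overall = character(0),
    joint = "joint",
    grasp = "grasp_type",
    subject = "subject",
    task_subject = c("grasp_type", "subject"),
    by
  )
  missing_cols <- setdiff(groups, names(results))
  if (length(missing_cols)) {
    abort(paste("unknown grouping column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  if (nrow(results) == 0) {
    warn("no scored trials to aggregate")
    return(tibble())
  }
  results %>%
    group_by(across(all_of(groups))) %>%
    summarise(
      n = dplyr::n(),
      accuracy_mean = 100 * mean(.data$rho),
      accuracy_sd = 100 * sd(.data$rho),
      error_mean = mean(1 - abs(.data$rho)),
      error_sd = sd(1 - abs(.data$rho)),
      .groups = "drop"
    ) %>%
    mutate(accuracy_sd = ifelse(is.na(.data$accuracy_sd), 0, .data$accuracy_sd),
           error_sd = ifelse(is.na(.data$error_sd), 0, .data$error_sd))
}

#' Task-by-subject accuracy table for one fold
#'
#' Formats one fold's per-task, per-subject mean +/- sd accuracy as a wide
#' table (tasks in rows, subjects in columns), mirroring how per-fold decoding
#' performance is conventionally reported.
#'
#' @param cv A `synergy_cv`.
#' @param fold Which fold to tabulate.
#' @return A tibble, one row per task, character cells `"mm.m +/- ss.s%"`.
#' @export
representative_fold_table <- function(cv, fold = 1) {
  stopifnot(inherits(cv, "synergy_cv"))
  res <- dplyr::filter(cv$results, .data$fold == !!fold)
  if (nrow(res) == 0) abort("no such fold")
  agg <- aggregate_accuracy(res, by = c("grasp_type", "subject"))
  agg %>%
    mutate(cell = sprintf("%.1f +/- %.1f%%", .data$accuracy_mean,
                          .data$accuracy_sd),
           subject = paste0("subject_", .data$subject),
           task = paste0("task_", .data$grasp_type)) %>%
    select("task", "subject", "cell") %>%
    tidyr::pivot_wider(names_from = "subject", values_from = "cell") %>%
    arrange(.data$task)
}

#' Neural independency density of each synergy
#'
#' For every electrode, re-fits the weight regression using only the features
#' of that electrode and its nearest neighbors (scalp distance <= `radius`),
#' one fit per grasp task, and sums the squared regression coefficients over
#' coefficients and tasks: `D_n(e) = sum_k sum_m beta_mk^2` for synergy n. A
#' large density marks an electrode neighborhood whose activity carries that
#' synergy's weights. A correlation statistic (mean squared Pearson
#' correlation between the neighborhood's features and the synergy weights,
#' summed over tasks) is reported alongside.
#'
#' The neighborhood features pass through the same reduction the whole-scalp
#' decoder uses — PCA retaining `pca_rule` of their variance — and the
#' retained component scores are standardized before the regression, so the
#' squared coefficients of different neighborhoods are on a common scale
#' (otherwise a low-variance, uninformative neighborhood would need huge
#' coefficients and dominate the map for the wrong reason).
#'
#' @param features An unreduced `feature_matrix` (channel provenance intact).
#' @param weights `synergy_weights` aligned with the feature rows.
#' @param montage Electrode montage (defaults to [gamma_montage_32()]).
#' @param radius Neighborhood radius in montage units.
#' @param per_task One regression per grasp type (default, matching the
#'   decoder); pooled otherwise.
#' @param pca_rule Variance fraction retained by the per-neighborhood PCA;
#'   `NULL` regresses on the raw (centered, unstandardized) neighborhood
#'   features instead, which exposes the plain sum-of-squared-coefficients
#'   statistic directly.
#' @return A tibble of class `independency_map`: electrode, x, y, synergy,
#'   density, mean_sq_corr, band.
#' @export
independency_density <- function(features, weights,
                                 montage = gamma_montage_32(), radius = 0.25,
                                 per_task = TRUE, pca_rule = 0.9) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(weights, "synergy_weights"))
  if (!is.null(features$reduction)) {
    abort("independency maps need unreduced per-electrode features")
  }
  if (nrow(features$X) != nrow(weights$C)) {
    abort("feature and weight row counts differ")
  }
  validate_montage(montage)
  chans <- unique(features$provenance$channel)
  missing <- setdiff(chans, montage$channel)
  if (length(missing)) {
    abort(paste("montage lacks position(s) for:", paste(missing, collapse = ", ")))
  }
  nb <- electrode_neighborhoods(montage, radius)
  grasp <- features$trial_index$grasp_type
  tasks <- if (per_task) sort(unique(grasp)) else NA_integer_
  n_syn <- ncol(weights$C)

  # component count capped well below the per-task row count so the
  # regressions never interpolate
  min_rows <- if (per_task) min(table(grasp)) else nrow(features$X)
  k_cap <- max(1L, min_rows %/% 10L)
  rows_out <- lapply(chans, function(e) {
    hood <- intersect(nb[[e]], chans)
    if (length(hood) == 0) {
      abort(paste("no neighborhood features for electrode", e))
    }
    sub <- fm_select_channels(features, hood)
    if (is.null(pca_rule)) {
      Z <- sub$X
    } else {
      red <- fit_feature_reducer(sub, rule = pca_rule)
      if (red$k > k_cap) {
        red$k <- k_cap
        red$loadings <- red$loadings[, seq_len(k_cap), drop = FALSE]
      }
      Z <- apply_feature_reducer(sub, red)$X
      zsd <- apply(Z, 2, sd)
      Z <- sweep(Z, 2, pmax(zsd, .Machine$double.eps), `/`)
    }
    D <- numeric(n_syn)
    R <- numeric(n_syn)
    for (k in tasks) {
      rows <- if (per_task) which(grasp == k) else seq_len(nrow(Z))
      Zk <- sweep(Z[rows, , drop = FALSE], 2,
                  colMeans(Z[rows, , drop = FALSE]))
      Ck <- weights$C[rows, , drop = FALSE]
      Ck <- sweep(Ck, 2, colMeans(Ck))
      B <- lstsq_minnorm(Zk, Ck)
      D <- D + colSums(B^2)
      cors <- suppressWarnings(cor(Zk, Ck))
      cors[is.na(cors)] <- 0
      R <- R + colMeans(cors^2)
    }
    pos <- montage[match(e, montage$channel), ]
    tibble(electrode = e, x = pos$x, y = pos$y,
           synergy = seq_len(n_syn), density = D, mean_sq_corr = R)
  })
  out <- dplyr::bind_rows(rows_out)
  out$band_lo <- features$band[1]
  out$band_hi <- features$band[2]
  class(out) <- c("independency_map", class(out))
  attr(out, "montage") <- montage
  out
}

#' Band-specific synergy modulation maps
#'
#' Repeats the electrode-neighborhood regression of [independency_density()]
#' with features restricted to each frequency band, yielding one independency
#' map per band (delta/theta/mu/beta/gamma by default). Feature extraction is
#' redone per band from the preprocessed EEG.
#'
#' @param cohort A `grasp_cohort`.
#' @param bands Named list of frequency intervals (default [eeg_bands()]).
#' @param subjects Subject indices whose trials are used for the fits
#'   (default: all).
#' @param threshold Synergy-selection threshold for the weights.
#' @param radius Neighborhood radius.
#' @param per_task Per-grasp-type regressions (default).
#' @return A tibble of class `independency_map` with an extra `band` column;
#'   empty tibble for an empty band list.
#' @export
band_modulation <- function(cohort, bands = eeg_bands(), subjects = NULL,
                            threshold = 0.85, radius = 0.25, per_task = TRUE) {
  stopifnot(inherits(cohort, "grasp_cohort"))
  if (length(bands) == 0) return(tibble())
  filt <- c(0.1, 56)
  for (b in bands) {
    if (b[1] < filt[1] - 1e-9 || b[2] > filt[2] + 1e-9) {
      abort("all bands must lie within the 0.1-56 Hz filter range")
    }
  }
  subjects <- subjects %||% seq_along(cohort$subjects)
  vm <- cohort_velocity(cohort)
  rows <- which(vm$trial_index$subject %in% subjects)
  vm <- vm_subset(vm, rows)
  syn <- select_synergies(synergy_svd(vm), threshold)
  W <- project_weights(vm, syn)
  montage <- cohort$subjects[[1]]$eeg$montage
  pre <- lapply(cohort$subjects[subjects], function(s) preprocess_eeg(s$eeg))

  maps <- purrr::imap(bands, function(band, name) {
    parts <- purrr::map2(pre, subjects, function(ses, i) {
      fm <- extract_features(ses, epoch_s = cohort$protocol$epoch_s,
                             band = band)
      fm$trial_index$subject <- i
      fm
    })
    X <- do.call(rbind, lapply(parts, `[[`, "X"))
    ti <- dplyr::bind_rows(lapply(parts, `[[`, "trial_index"))
    fm <- new_feature_matrix(X, parts[[1]]$provenance, band, ti,
                             parts[[1]]$settings)
    m <- independency_density(fm, W, montage = montage, radius = radius,
                              per_task = per_task)
    m$band <- name
    m
  })
  out <- dplyr::bind_rows(maps)
  class(out) <- c("independency_map", class(out))
  attr(out, "montage") <- montage
  out
}
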
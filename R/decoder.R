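#' Fit the neural decoder (multivariate linear regression)
#'
#' Solves `C = X beta` in the least-squares sense on training trials: `beta`
#' is the minimum-norm minimizer of the Frobenius residual, computed from the
#' SVD of `X`. Both sides are mean-centered within each fit and the training
#' means are restored at prediction time, which plays the role of an
#' intercept without exposing one as a coefficient (a slope-only regression
#' of uncentered weights on centered features would be biased by the mean
#' weight of each task). By default one regression is fitted per grasp type
#' (`per_task = TRUE`); the pooled alternative fits a single map for all
#' trials.
#'
#' @param features A reduced `feature_matrix` of training trials (rows must
#'   align with `weights`).
#' @param weights A `synergy_weights` of the same training trials.
#' @param per_task Fit one coefficient matrix per grasp type.
#' @return An object of class `synergy_decoder`: coefficient matrices, the
#'   feature reducer reference, and per-fit rank/condition diagnostics.
#' @export
fit_decoder <- function(features, weights, per_task = TRUE) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(weights, "synergy_weights"))
  if (nrow(features$X) != nrow(weights$C)) {
    abort("feature and weight row counts differ")
  }
  grasp <- features$trial_index$grasp_type
  if (per_task && is.null(grasp)) {
    abort("per-task fitting requires grasp_type in the feature trial index")
  }
  tasks <- if (per_task) sort(unique(grasp)) else NA_integer_
  fits <- lapply(tasks, function(k) {
    rows <- if (per_task) which(grasp == k) else seq_len(nrow(features$X))
    X <- features$X[rows, , drop = FALSE]
    C <- weights$C[rows, , drop = FALSE]
    x_mean <- colMeans(X)
    c_mean <- colMeans(C)
    B <- lstsq_minnorm(sweep(X, 2, x_mean), sweep(C, 2, c_mean))
    if (attr(B, "rank_deficient")) {
      warn(paste0("rank-deficient feature matrix",
                  if (per_task) paste0(" for task ", k),
                  "; minimum-norm solution used"))
    }
    attr(B, "x_mean") <- x_mean
    attr(B, "c_mean") <- c_mean
    B
  })
  names(fits) <- if (per_task) paste0("task", tasks) else "pooled"
  diagnostics <- tibble(
    task = if (per_task) tasks else NA_integer_,
    rank = vapply(fits, attr, integer(1), "rank"),
    cond = vapply(fits, attr, numeric(1), "cond")
  )
  strip <- function(b) {
    out <- matrix(as.numeric(b), nrow(b), ncol(b))
    out
  }
  structure(list(beta = lapply(fits, strip),
                 x_means = lapply(fits, attr, "x_mean"),
                 c_means = lapply(fits, attr, "c_mean"),
                 per_task = per_task, tasks = tasks,
                 reducer = features$reduction,
                 n_syn = ncol(weights$C),
                 diagnostics = diagnostics),
            class = "synergy_decoder")
}

#' @export
print.synergy_decoder <- function(x, ...) {
  cat("<synergy_decoder> ",
      if (x$per_task) paste0(length(x$beta), " per-task fits") else "pooled fit",
      ", ", nrow(x$beta[[1]]), " features -> ", x$n_syn, " synergy weights\n",
      sep = "")
  invisible(x)
}

#' Decode synergy weights for new trials
#'
#' Applies the fitted coefficient matrices to the (reduced) neural features of
#' held-out trials: `C_hat = X beta`. The features must have been produced
#' with the same training-fit reducer the decoder stores; a mismatch is an
#' error (this is what prevents accidentally re-fitting the reduction on test
#' subjects).
#'
#' @param features Reduced `feature_matrix` of test trials.
#' @param model A `synergy_decoder`.
#' @return A `synergy_weights` of decoded weights.
#' @export
predict_weights <- function(features, model) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(model, "synergy_decoder"))
  if (!is.null(model$reducer)) {
    red <- features$reduction
    if (is.null(red) ||
        !isTRUE(all.equal(red$center, model$reducer$center)) ||
        !isTRUE(all.equal(red$loadings, model$reducer$loadings))) {
      abort("test features were not produced with the decoder's training-fit reducer")
    }
  }
  n <- nrow(features$X)
  C <- matrix(0, n, model$n_syn)
  if (model$per_task) {
    grasp <- features$trial_index$grasp_type
    if (is.null(grasp)) abort("per-task decoding requires grasp_type labels")
    missing <- setdiff(unique(grasp), model$tasks)
    if (length(missing)) {
      abort(paste("no fitted regression for task(s):",
                  paste(missing, collapse = ", ")))
    }
    for (k in model$tasks) {
      rows <- which(grasp == k)
      if (length(rows)) {
        nm <- paste0("task", k)
        C[rows, ] <- sweep(features$X[rows, , drop = FALSE], 2,
                           model$x_means[[nm]]) %*% model$beta[[nm]]
        C[rows, ] <- sweep(C[rows, , drop = FALSE], 2,
                           model$c_means[[nm]], `+`)
      }
    }
  } else {
    C <- sweep(sweep(features$X, 2, model$x_means[["pooled"]]) %*%
                 model$beta[["pooled"]], 2, model$c_means[["pooled"]], `+`)
  }
  new_synergy_weights(C, features$trial_index)
}

#' Reconstruct kinematics from decoded weights
#'
#' Convenience wrapper: linearly combines decoded weights with the synergies
#' extracted from the training set (see [reconstruct_velocity()]).
#'
#' @param weights Decoded `synergy_weights`.
#' @param synergies The training-set `synergy_set`.
#' @return A `velocity_matrix` of decoded velocities.
#' @export
decode_kinematics <- function(weights, synergies) {
  reconstruct_velocity(weights, synergies)
}

#' Cross-subject cross-validation of the full decoding pipeline
#'
#' Runs `n_folds` independent shuffled half/half subject splits (5 train / 5
#' test for a ten-subject cohort; floor/ceil for odd counts). In every fold,
#' synergy extraction, the PCA feature reduction and the regression are fitted
#' on training subjects only; test subjects' kinematics are then decoded from
#' their EEG alone and scored per trial and joint with the Pearson correlation
#' between recorded and decoded velocity epochs.
#'
#' Trials whose recorded joint trace is constant (correlation undefined) are
#' flagged (`flagged = TRUE`, `rho = NA`) rather than scored.
#'
#' @param cohort A `grasp_cohort`.
#' @param n_folds Number of shuffled splits.
#' @param seed Integer seed controlling the splits.
#' @param threshold Cumulative-variance synergy selection threshold.
#' @param pca_rule Feature-reduction rule (see [fit_feature_reducer()]).
#' @param band Feature frequency band (Hz).
#' @param per_task One regression per grasp type (default) or pooled.
#' @param features Optional precomputed cohort [cohort_features()] matrix
#'   (unreduced, full band); computed if missing.
#' @param velocity Optional precomputed [cohort_velocity()] matrix.
#' @return An object of class `synergy_cv`: list with `results` (tibble: fold,
#'   subject, grasp_type, trial_id, joint, rho, flagged), `folds` (per-fold
#'   metadata: train subjects, synergy count, PCA components, condition
#'   numbers) and `settings`.
#' @export
cross_validate <- function(cohort, n_folds = 10, seed = 1, threshold = 0.85,
                           pca_rule = 0.9, band = c(0.1, 56), per_task = TRUE,
                           features = NULL, velocity = NULL) {
  stopifnot(inherits(cohort, "grasp_cohort"))
  if (!is_count(n_folds)) abort("n_folds must be a positive integer")
  n_sub <- length(cohort$subjects)
  if (n_sub < 2) abort("at least 2 subjects are required")
  features <- features %||% cohort_features(cohort, band = band)
  velocity <- velocity %||% cohort_velocity(cohort)
  if (!identical(nrow(features$X), nrow(velocity$V))) {
    abort("feature and velocity matrices disagree on trial count")
  }
  lay <- velocity$layout
  E <- lay$epoch_samples
  n_train <- n_sub %/% 2L

  res_list <- vector("list", n_folds)
  meta_list <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    set.seed(derive_seed(seed, f))
    perm <- sample(n_sub)
    train_sub <- sort(perm[seq_len(n_train)])
    test_sub <- sort(perm[(n_train + 1):n_sub])
    tr_rows <- which(velocity$trial_index$subject %in% train_sub)
    te_rows <- which(velocity$trial_index$subject %in% test_sub)

    decomp <- synergy_svd(vm_subset(velocity, tr_rows))
    syn <- select_synergies(decomp, threshold)
    C_train <- project_weights(vm_subset(velocity, tr_rows), syn)

    reducer <- fit_feature_reducer(features, rows = tr_rows, rule = pca_rule)
    stopifnot(all(reducer$fit_rows %in% tr_rows))   # leakage guard
    X_tr <- apply_feature_reducer(fm_subset(features, tr_rows), reducer)
    model <- fit_decoder(X_tr, C_train, per_task = per_task)

    X_te <- apply_feature_reducer(fm_subset(features, te_rows), reducer)
    C_hat <- predict_weights(X_te, model)
    decoded <- reconstruct_velocity(C_hat, syn)
    recorded <- vm_subset(velocity, te_rows)

    rho <- matrix(NA_real_, length(te_rows), lay$n_joints)
    for (j in seq_len(lay$n_joints)) {
      cols <- (j - 1L) * E + seq_len(E)
      rho[, j] <- row_cor(recorded$V[, cols, drop = FALSE],
                          decoded$V[, cols, drop = FALSE])
    }
    ti <- recorded$trial_index
    res_list[[f]] <- tibble(
      fold = f,
      subject = rep(ti$subject, lay$n_joints),
      grasp_type = rep(ti$grasp_type, lay$n_joints),
      trial_id = rep(ti$trial_id, lay$n_joints),
      joint = rep(lay$joint_labels, each = length(te_rows)),
      rho = as.numeric(rho)
    )
    meta_list[[f]] <- tibble(
      fold = f,
      train_subjects = paste(train_sub, collapse = ","),
      test_subjects = paste(test_sub, collapse = ","),
      n_syn = syn$n_syn,
      pca_components = reducer$k,
      max_cond = max(model$diagnostics$cond)
    )
  }
  results <- dplyr::bind_rows(res_list)
  results$flagged <- is.na(results$rho)
  structure(list(results = results,
                 folds = dplyr::bind_rows(meta_list),
                 settings = list(n_folds = n_folds, seed = seed,
                                 threshold = threshold, pca_rule = pca_rule,
                                 band = band, per_task = per_task,
                                 joint_labels = lay$joint_labels)),
            class = "synergy_cv")
}

#' @export
print.synergy_cv <- function(x, ...) {
  ok <- x$results$rho[!x$results$flagged]
  cat("<synergy_cv> ", nrow(x$folds), " folds, ",
      nrow(x$results), " (trial x joint) scores; mean accuracy ",
      sprintf("%.1f%% +/- %.1f%%", 100 * mean(ok), 100 * sd(ok)), "\n",
      sep = "")
  invisible(x)
}
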
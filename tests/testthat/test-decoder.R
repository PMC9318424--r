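make_fm <- function(X, grasp = rep(1L, nrow(X))) {
  synergydecoder:::new_feature_matrix(
    X, tibble::tibble(column = seq_len(ncol(X)), channel = "A",
                      window = seq_len(ncol(X)), band_lo = 0.1, band_hi = 56),
    c(0.1, 56),
    tibble::tibble(trial_id = seq_len(nrow(X)), grasp_type = grasp))
}

test_that("the fitted coefficients match a normal-equations oracle", {
  set.seed(11)
  X <- matrix(rnorm(40 * 8), 40, 8)
  B0 <- matrix(rnorm(8 * 3), 8, 3)
  C <- X %*% B0
  mod <- fit_decoder(make_fm(X), synergy_weights(C), per_task = FALSE)
  expect_equal(mod$beta$pooled, B0, tolerance = 1e-8)
  oracle <- solve(crossprod(X), crossprod(X, C))
  expect_equal(mod$beta$pooled, oracle, tolerance = 1e-8)

  # per-task fitting solves each task's system independently
  grasp <- rep(1:2, each = 20)
  modt <- fit_decoder(make_fm(X, grasp), synergy_weights(C))
  for (k in 1:2) {
    rows <- which(grasp == k)
    expect_equal(modt$beta[[paste0("task", k)]],
                 solve(crossprod(X[rows, ]), crossprod(X[rows, ], C[rows, ])),
                 tolerance = 1e-8)
  }
})

test_that("degenerate fits behave: zero column, zero targets, rank warnings", {
  set.seed(2)
  X <- matrix(rnorm(20 * 5), 20, 5)
  X[, 3] <- 0
  C <- matrix(rnorm(20 * 2), 20, 2)
  expect_warning(
    mod <- fit_decoder(make_fm(X), synergy_weights(C), per_task = FALSE),
    "rank-deficient")
  expect_equal(mod$beta$pooled[3, ], c(0, 0))

  mod0 <- fit_decoder(make_fm(X[, -3]), synergy_weights(C * 0),
                      per_task = FALSE)
  expect_true(all(mod0$beta$pooled == 0))

  expect_error(fit_decoder(make_fm(X), synergy_weights(C[1:10, ])),
               "row counts")
})

test_that("prediction is linear and guards the reducer provenance", {
  set.seed(3)
  X <- matrix(rnorm(30 * 6), 30, 6)
  C <- X %*% matrix(rnorm(12), 6, 2)
  fm <- make_fm(X)
  red <- fit_feature_reducer(fm, rule = 6L)
  Z <- apply_feature_reducer(fm, red)
  mod <- fit_decoder(Z, synergy_weights(C), per_task = FALSE)

  Zt <- apply_feature_reducer(synergydecoder:::fm_subset(fm, c(1, 1, 2)), red)
  pred <- predict_weights(Zt, mod)
  expect_equal(pred$C[1, ], pred$C[2, ])                 # duplicated row
  # a trial sitting at the training feature mean decodes to the mean weight
  zero_fm <- synergydecoder:::fm_subset(fm, 1:2)
  zero_fm$X[] <- red$center[col(zero_fm$X)]
  predz <- predict_weights(apply_feature_reducer(zero_fm, red), mod)
  expect_equal(predz$C[1, ], mod$c_means$pooled, tolerance = 1e-10,
               ignore_attr = TRUE)
  # and with centered targets a zero feature row decodes to zero weights
  mod0 <- fit_decoder(Z, synergy_weights(sweep(C, 2, colMeans(C))),
                      per_task = FALSE)
  predz0 <- predict_weights(apply_feature_reducer(zero_fm, red), mod0)
  expect_equal(predz0$C, matrix(0, 2, 2), tolerance = 1e-10)

  other <- fit_feature_reducer(synergydecoder:::fm_subset(fm, 1:15), rule = 3L)
  Zo <- apply_feature_reducer(fm, other)
  expect_error(predict_weights(Zo, mod), "training-fit reducer")
})

test_that("cross-validation splits are disjoint, balanced and seed-stable", {
  ch <- noisy_cohort()
  cv1 <- cross_validate(ch, n_folds = 3, seed = 5)
  cv2 <- cross_validate(ch, n_folds = 3, seed = 5)
  expect_identical(cv1$results, cv2$results)
  expect_identical(cv1$folds, cv2$folds)
  cv3 <- cross_validate(ch, n_folds = 3, seed = 6)
  expect_false(identical(cv1$folds$train_subjects, cv3$folds$train_subjects))

  for (f in seq_len(nrow(cv1$folds))) {
    tr <- as.integer(strsplit(cv1$folds$train_subjects[f], ",")[[1]])
    te <- as.integer(strsplit(cv1$folds$test_subjects[f], ",")[[1]])
    expect_length(intersect(tr, te), 0)
    expect_setequal(c(tr, te), 1:2)
  }
  expect_true(all(cv1$results$rho >= -1 & cv1$results$rho <= 1,
                  na.rm = TRUE))
  expect_error(cross_validate(ch, n_folds = 0), "positive integer")
})

test_that("no training parameter depends on test-subject data", {
  ch <- noisy_cohort()
  cv_ref <- cross_validate(ch, n_folds = 1, seed = 5)
  test_subject <- as.integer(cv_ref$folds$test_subjects[1])

  # corrupt the held-out subject's recordings; every fitted quantity
  # (synergy count, PCA size, conditioning) must be unchanged
  ch2 <- ch
  set.seed(99)
  ch2$subjects[[test_subject]]$eeg$data <-
    ch2$subjects[[test_subject]]$eeg$data +
    matrix(rnorm(length(ch2$subjects[[test_subject]]$eeg$data), 0, 5),
           nrow(ch2$subjects[[test_subject]]$eeg$data))
  ch2$subjects[[test_subject]]$kinematics$angles <-
    ch2$subjects[[test_subject]]$kinematics$angles * 1.3
  cv_mod <- cross_validate(ch2, n_folds = 1, seed = 5)

  expect_identical(cv_ref$folds$train_subjects, cv_mod$folds$train_subjects)
  expect_identical(cv_ref$folds$n_syn, cv_mod$folds$n_syn)
  expect_identical(cv_ref$folds$pca_components, cv_mod$folds$pca_components)
  expect_equal(cv_ref$folds$max_cond, cv_mod$folds$max_cond, tolerance = 1e-12)
  # while the test-side scores do change
  expect_false(isTRUE(all.equal(cv_ref$results$rho, cv_mod$results$rho)))
})

test_that("decoding accuracy improves to ~1 as feature noise vanishes", {
  proto <- small_protocol(n_reps = 6)
  acc <- vapply(c(1, 0.1, 0), function(sf) {
    gt <- make_ground_truth(n_syn = 3, n_joints = 4, epoch_samples = 250,
                            n_grasps = 3, seed = 3,
                            noise_sd_kin = 0, noise_sd_feat = sf)
    ch <- generate_cohort(gt, n_subjects = 2, protocol = proto, seed = 4)
    cv <- cross_validate(ch, n_folds = 2, seed = 9, pca_rule = 3L,
                         threshold = 0.999)
    mean(cv$results$rho, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(acc) > 0))
  expect_gt(acc[3], 0.99)
})
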
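test_that("ground truth synergies are orthonormal and deterministic", {
  gt <- make_ground_truth(seed = 7)
  expect_equal(dim(gt$synergies), c(6, 2500))
  G <- tcrossprod(gt$synergies)
  expect_lt(max(abs(G - diag(6))), 1e-8)

  gt1 <- make_ground_truth(n_syn = 1, n_joints = 1, epoch_samples = 4,
                           n_grasps = 2, seed = 3)
  expect_equal(sum(gt1$synergies^2), 1, tolerance = 1e-12)

  expect_identical(make_ground_truth(seed = 7), make_ground_truth(seed = 7))
  expect_error(make_ground_truth(n_syn = 5, n_joints = 1, epoch_samples = 4),
               "exceed")
  # weight covariance is diagonal with non-negative entries: psd by construction
  expect_true(all(gt$weight_sds >= 0))
})

test_that("a full-protocol subject has 180 matched cue events", {
  gt <- make_ground_truth(seed = 2)
  sub <- generate_subject(gt, grasp_protocol(), subject_seed = 4)
  expect_equal(nrow(sub$kinematics$events), 180)
  expect_equal(nrow(sub$eeg$events), 180)
  expect_identical(sub$kinematics$events$cue_on_s, sub$eeg$events$cue_on_s)
  expect_equal(sort(unique(sub$kinematics$events$grasp_type)), 1:6)
  expect_equal(as.integer(table(sub$kinematics$events$grasp_type)),
               rep(30L, 6))
})

test_that("subject generation is seed-deterministic, cohorts differ by seed", {
  gt <- clean_gt()
  s1 <- generate_subject(gt, small_protocol(), subject_seed = 11)
  s2 <- generate_subject(gt, small_protocol(), subject_seed = 11)
  expect_identical(s1, s2)

  c1 <- generate_cohort(gt, 2, small_protocol(), seed = 1)
  c2 <- generate_cohort(gt, 2, small_protocol(), seed = 2)
  expect_false(identical(c1$subjects[[1]]$weights, c2$subjects[[1]]$weights))
  expect_identical(c1$ground_truth, c2$ground_truth)
  expect_identical(generate_cohort(gt, 2, small_protocol(), seed = 1), c1)

  expect_error(generate_cohort(gt, n_subjects = 1), "2")
})

test_that("noiseless kinematics lie exactly in the synergy row space", {
  sub <- clean_subject()
  gt <- clean_gt()
  vm <- build_velocity_matrix(segment_trials(sub$kinematics, 2))
  P <- crossprod(gt$synergies)           # projector onto the synergy span
  expect_lt(max(abs(vm$V - vm$V %*% P)), 1e-8)
  d <- svd(vm$V)$d
  expect_equal(sum(d > 1e-8 * d[1]), gt$n_syn)
})

test_that("band-power features of noiseless EEG equal baseline + coupling x weights", {
  sub <- clean_subject()
  gt <- clean_gt()
  fm <- extract_features(sub$eeg, epoch_s = 2)
  fc <- feature_coupling(gt, small_protocol())
  pred <- matrix(fc$baseline, nrow(fm$X), length(fc$baseline), byrow = TRUE) +
    sub$weights %*% t(fc$coupling)
  rel <- abs(fm$X - pred) / pmax(abs(pred), 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("excluded-trial flags propagate and downstream stages skip them", {
  gt <- clean_gt()
  set.seed(1)
  sub <- generate_subject(gt, small_protocol(), subject_seed = 3,
                          exclusion_rate = 0.3)
  n_excl <- sum(sub$kinematics$events$excluded)
  expect_gt(n_excl, 0)
  ep <- segment_trials(sub$kinematics, 2)
  expect_length(ep, nrow(sub$kinematics$events) - n_excl)
  fm <- extract_features(sub$eeg, epoch_s = 2)
  expect_equal(nrow(fm$X), nrow(sub$eeg$events) - n_excl)
})
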
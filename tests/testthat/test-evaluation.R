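test_that("Pearson rho and the 1 - |rho| error follow their definitions", {
  x <- rnorm(50)
  expect_equal(pearson_rho(x, x), 1)
  expect_equal(pearson_rho(x, -x), -1)
  expect_equal(round(pearson_rho(c(1, 2, 3), c(1, 2, 4)), 3), 0.982)
  expect_error(pearson_rho(1:5, 1:4), "equal length")
  expect_error(pearson_rho(1:2, 2:3), "at least 3")
  expect_error(pearson_rho(rep(1, 5), rnorm(5)),
               class = "synergydecoder_constant_series")

  expect_equal(decoding_error(1), 0)
  expect_equal(decoding_error(-1), 0)     # anti-correlation is zero error
  expect_equal(decoding_error(0.3), 0.7)
  expect_error(decoding_error(1.5), "-1, 1")
  # symmetry under sign flip of the decoded series
  r <- runif(20, -1, 1)
  expect_equal(decoding_error(r), decoding_error(-r))
})

test_that("accuracy aggregation reproduces hand-computed means and sds", {
  one <- tibble::tibble(subject = 1, grasp_type = 1, trial_id = 1,
                        joint = "TMCP", rho = 0.8, flagged = FALSE)
  agg1 <- aggregate_accuracy(one)
  expect_equal(agg1$accuracy_mean, 80)
  expect_equal(agg1$accuracy_sd, 0)

  two <- dplyr::bind_rows(one, dplyr::mutate(one, trial_id = 2, rho = 0.6))
  agg2 <- aggregate_accuracy(two)
  expect_equal(agg2$accuracy_mean, 70)
  expect_equal(agg2$accuracy_sd, 100 * stats::sd(c(0.8, 0.6)))
  expect_equal(agg2$error_mean, mean(1 - abs(c(0.8, 0.6))))

  # grouping partitions the records and means stay weighted-consistent
  set.seed(8)
  res <- tibble::tibble(
    subject = sample(1:3, 200, TRUE), grasp_type = sample(1:4, 200, TRUE),
    trial_id = 1:200, joint = sample(hand_joint_labels(), 200, TRUE),
    rho = runif(200, -1, 1), flagged = FALSE)
  byg <- aggregate_accuracy(res, "grasp")
  expect_equal(sum(byg$n), nrow(res))
  overall <- aggregate_accuracy(res)$accuracy_mean
  expect_equal(sum(byg$n * byg$accuracy_mean) / sum(byg$n), overall)

  # flagged trials are excluded
  res$flagged[1:50] <- TRUE
  expect_equal(aggregate_accuracy(res)$n, 150)
  expect_error(aggregate_accuracy(res, "nope"), "unknown grouping")
})

test_that("the independency density realizes the squared-coefficient sum", {
  # single electrode, single feature, single task: feature = x, weights = 2x
  # => beta = 2 and density = 4 (raw-feature path)
  set.seed(5)
  x <- rnorm(30)
  mont <- gamma_montage_32()[1, ]
  fm <- synergydecoder:::new_feature_matrix(
    matrix(x, 30, 1),
    tibble::tibble(column = 1L, channel = mont$channel, window = 1L,
                   band_lo = 0.1, band_hi = 56),
    c(0.1, 56), tibble::tibble(trial_id = 1:30, grasp_type = 1L))
  W <- synergy_weights(matrix(2 * x, 30, 1),
                       tibble::tibble(trial_id = 1:30, grasp_type = 1L))
  m <- independency_density(fm, W, montage = mont, pca_rule = NULL)
  expect_equal(m$density, 4, tolerance = 1e-10)
  expect_equal(m$mean_sq_corr, 1, tolerance = 1e-10)

  # constant weights within the task: all centered targets zero => D = 0
  W0 <- synergy_weights(matrix(1, 30, 1),
                        tibble::tibble(trial_id = 1:30, grasp_type = 1L))
  expect_equal(independency_density(fm, W0, montage = mont,
                                    pca_rule = NULL)$density, 0)
})

test_that("densities are non-negative and invariant to task and channel order", {
  ch <- noisy_cohort()
  fm <- cohort_features(ch)
  W <- synergy_weights(do.call(rbind, lapply(ch$subjects, `[[`, "weights")),
                       fm$trial_index)
  mont <- ch$subjects[[1]]$eeg$montage
  m1 <- independency_density(fm, W, montage = mont)
  expect_true(all(m1$density >= 0))

  # shuffle trial order (hence task order) consistently
  set.seed(1)
  perm <- sample(nrow(fm$X))
  m2 <- independency_density(synergydecoder:::fm_subset(fm, perm),
                             synergy_weights(W$C[perm, , drop = FALSE],
                                             fm$trial_index[perm, ]),
                             montage = mont)
  expect_equal(m1$density, m2$density, tolerance = 1e-8)

  # reorder feature columns (electrode blocks)
  cols <- order(fm$provenance$window, fm$provenance$channel)
  fm3 <- fm
  fm3$X <- fm$X[, cols]
  fm3$provenance <- fm$provenance[cols, ]
  fm3$provenance$column <- seq_len(ncol(fm3$X))
  m3 <- independency_density(fm3, W, montage = mont)
  m3 <- m3[order(match(m3$electrode, m1$electrode), m3$synergy), ]
  expect_equal(m1$density, m3$density, tolerance = 1e-8)
})

test_that("planted couplings are recovered as density maxima in their neighborhoods", {
  dp <- default_pair()
  W <- synergy_weights(do.call(rbind, lapply(dp$cohort$subjects, `[[`,
                                             "weights")),
                       dp$features$trial_index)
  imap <- independency_density(dp$features, W)
  nb <- electrode_neighborhoods()
  for (j in seq_len(dp$gt$n_syn)) {
    dj <- dplyr::filter(imap, .data$synergy == j)
    top <- dj$electrode[which.max(dj$density)]
    expect_true(top %in% nb[[dp$gt$coupling$centers[j]]],
                info = paste("synergy", j))
  }
})

test_that("band modulation maps isolate the encoding band", {
  dp <- default_pair()
  bm <- band_modulation(dp$cohort, bands = list(mu = c(8, 12),
                                                beta = c(18, 30)))
  mx <- tapply(bm$density, bm$band, max)
  expect_gt(mx[["mu"]] / mx[["beta"]], 2)   # carrier lives in the mu band

  expect_equal(nrow(band_modulation(dp$cohort, bands = list())), 0)
  expect_error(band_modulation(dp$cohort, bands = list(c(50, 80))), "filter")

  # the full filter range reproduces the plain independency computation
  full <- band_modulation(dp$cohort, bands = list(full = c(0.1, 56)),
                          subjects = 1:2)
  vm <- dp$velocity
  syn <- select_synergies(synergy_svd(vm))
  W <- project_weights(vm, syn)
  direct <- independency_density(dp$features, W,
                                 montage = dp$cohort$subjects[[1]]$eeg$montage)
  expect_equal(full$density, direct$density, tolerance = 1e-6)
})

test_that("the representative-fold table mirrors task-by-subject accuracy", {
  ch <- noisy_cohort()
  cv <- cross_validate(ch, n_folds = 2, seed = 5)
  tab <- representative_fold_table(cv, fold = 1)
  expect_equal(nrow(tab), 3)               # one row per grasp type
  expect_equal(ncol(tab), 2)               # task + one held-out subject
  expect_true(all(grepl("%$", unlist(tab[, -1]))))
  expect_error(representative_fold_table(cv, fold = 99), "no such fold")
})
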
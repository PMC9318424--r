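test_that("sliding-window count matches the closed form and brute force", {
  w <- sliding_windows(512, 256, 500, 375)
  expect_equal(nrow(w), 13)                 # 13 features per electrode
  expect_equal(w$start[1], 1)
  expect_equal(w$end[1] - w$start[1] + 1, 128)
  expect_equal(unique(diff(w$start)), 32)

  expect_equal(nrow(sliding_windows(128, 256, 500, 375)), 1)  # epoch == width

  brute_count <- function(E, width, step) {
    n <- 0; o <- 1
    while (o + width - 1 <= E) { n <- n + 1; o <- o + step }
    n
  }
  for (E in c(128, 129, 191, 192, 300, 511, 512, 513)) {
    for (pars in list(c(500, 375), c(500, 250), c(250, 125))) {
      width <- round(pars[1] / 1000 * 256); step <- width -
        round(pars[2] / 1000 * 256)
      got <- tryCatch(nrow(sliding_windows(E, 256, pars[1], pars[2])),
                      error = function(e) 0L)
      expect_equal(got, brute_count(E, width, step),
                   info = paste(E, pars[1], pars[2]))
    }
  }
  expect_error(sliding_windows(512, 256, 375, 500), "exceed")
})

test_that("band power integrates the PSD correctly (Parseval checks)", {
  expect_equal(band_power(rep(0, 128), 256, c(8, 12)), 0)

  x <- sin(2 * pi * 10 * (0:127) / 256)
  # trapezoid integration halves the band-edge bins, so a band whose edges
  # carry spectral mass under-counts; edges on low-power bins are exact
  expect_equal(band_power(x, 256, c(6, 14), normalize = FALSE), 0.5,
               tolerance = 0.01)
  expect_equal(band_power(x, 256, c(8, 12), normalize = FALSE), 0.5,
               tolerance = 0.2)             # mainlobe edges at 8 and 12 Hz

  set.seed(9)
  wn <- rnorm(512)
  tot <- band_power(wn, 256, c(0, 128), normalize = FALSE)
  expect_equal(tot, mean((wn * 0 + 1) * wn^2), tolerance = 0.35)
  expect_equal(tot / stats::var(wn), 1, tolerance = 0.1)

  # additivity over a contiguous partition of the filter range
  parts <- list(c(0.1, 4), c(4, 8), c(8, 12), c(12, 18), c(18, 30), c(30, 56))
  full <- band_power(wn, 256, c(0.1, 56), normalize = FALSE)
  pieces <- sum(vapply(parts, function(b)
    band_power(wn, 256, b, normalize = FALSE), 0))
  expect_equal(pieces, full, tolerance = 0.02)

  expect_true(band_power(rnorm(64), 256, c(8, 12)) >= 0)
  expect_error(band_power(x, 256, c(100, 200)), "rate/2")
})

test_that("preprocessing removes offset and trend and respects the passband", {
  ses <- toy_eeg_session()
  n <- nrow(ses$data)
  ses$data[, 1] <- 7.5                                  # constant offset
  ses$data[, 2] <- seq(0, 4, length.out = n)            # pure trend
  pre <- preprocess_eeg(ses)
  expect_lt(max(abs(pre$data[, 1])), 1e-6)
  expect_lt(max(abs(pre$data[, 2])), 0.05)

  # filter response measured on steady-state sinusoids (edges trimmed)
  gain_at <- function(f) {
    s <- toy_eeg_session()
    t <- (0:(nrow(s$data) - 1)) / s$rate
    s$data <- matrix(sin(2 * pi * f * t), ncol = 1)[, rep(1, 3)]
    out <- preprocess_eeg(s)$data[, 1]
    mid <- seq(round(length(out) * 0.3), round(length(out) * 0.7))
    sqrt(mean(out[mid]^2) / 0.5)
  }
  expect_lt(abs(20 * log10(gain_at(10))), 1)      # within 1 dB at 10 Hz
  expect_lt(20 * log10(gain_at(100)), -40)        # >= 40 dB down at 100 Hz

  ses2 <- toy_eeg_session(); ses2$resting <- NULL
  expect_error(preprocess_eeg(ses2), "resting")
})

test_that("feature extraction has the documented shape and is deterministic", {
  sub <- clean_subject()
  fm <- extract_features(sub$eeg, epoch_s = 2)
  expect_equal(ncol(fm$X), 32 * 13)
  expect_equal(nrow(fm$X), nrow(sub$eeg$events))
  expect_equal(nrow(fm$provenance), 416)
  expect_identical(fm$X, extract_features(sub$eeg, epoch_s = 2)$X)

  mu <- extract_features(sub$eeg, epoch_s = 2, band = c(8, 12))
  expect_equal(dim(mu$X), dim(fm$X))
  expect_equal(unique(mu$provenance$band_lo), 8)

  # two trials cut from identical signal stretches give identical rows
  toy <- toy_eeg_session()
  ft <- extract_features(toy, epoch_s = 2)
  expect_equal(ft$X[1, ], ft$X[2, ], tolerance = 1e-12)
})

test_that("the PCA reducer is train-fit, applies out of sample, and guards state", {
  set.seed(4)
  n <- 40
  lat <- matrix(rnorm(n * 2), n, 2)
  X <- lat %*% matrix(rnorm(2 * 10), 2, 10)   # exact rank 2
  fm <- synergydecoder:::new_feature_matrix(
    X, tibble::tibble(column = 1:10, channel = "A", window = 1:10,
                      band_lo = 0.1, band_hi = 56),
    c(0.1, 56), tibble::tibble(trial_id = 1:n, grasp_type = 1L))
  red <- fit_feature_reducer(fm, rule = 0.99)
  expect_equal(red$k, 2)

  # full-retention round trip reconstructs the centered features
  red_all <- fit_feature_reducer(fm, rule = 10L)
  Z <- apply_feature_reducer(fm, red_all)
  back <- Z$X %*% t(red_all$loadings)
  expect_equal(back, sweep(X, 2, colMeans(X)), tolerance = 1e-10,
               ignore_attr = TRUE)

  # fitting on training rows only, then projecting held-out rows
  red_tr <- fit_feature_reducer(fm, rows = 1:20, rule = 2L)
  expect_identical(red_tr$fit_rows, 1:20)
  Zte <- apply_feature_reducer(synergydecoder:::fm_subset(fm, 21:40), red_tr)
  expect_equal(nrow(Zte$X), 20)

  expect_error(apply_feature_reducer(fm, "unfitted"), "not been fitted")
  fm_bad <- synergydecoder:::fm_subset(fm, 1:5)
  fm_bad$X <- fm_bad$X[, 1:3]
  fm_bad$provenance <- fm_bad$provenance[1:3, ]
  expect_error(apply_feature_reducer(fm_bad, red), "does not match")
  expect_error(fit_feature_reducer(apply_feature_reducer(fm, red), rule = 0.9),
               "already reduced")
})
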
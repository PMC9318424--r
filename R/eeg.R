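#' Construct an EEG session
#'
#' @param data Numeric matrix, samples x channels (microvolts).
#' @param rate Sampling rate (Hz).
#' @param montage Tibble of channel names and 2-D scalp positions
#'   (`channel`, `x`, `y`); its row order defines the channel columns.
#' @param events Cue-event tibble shared with the kinematics session.
#' @param resting Length-2 integer vector, first/last sample index of the
#'   resting baseline segment.
#' @return An object of class `eeg_session`.
#' @export
new_eeg_session <- function(data, rate, montage = gamma_montage_32(),
                            events, resting) {
  data <- as.matrix(data)
  validate_montage(montage)
  if (ncol(data) != nrow(montage)) {
    abort("number of data columns must match the montage")
  }
  validate_events(events, n_samples = nrow(data), rate = rate)
  if (!is.null(resting)) {
    stopifnot(length(resting) == 2, resting[1] >= 1,
              resting[2] <= nrow(data), resting[1] <= resting[2])
  }
  colnames(data) <- montage$channel
  structure(list(data = data, rate = rate, montage = as_tibble(montage),
                 events = as_tibble(events), resting = resting,
                 preprocessed = FALSE),
            class = "eeg_session")
}

#' @export
print.eeg_session <- function(x, ...) {
  cat("<eeg_session> ", nrow(x$data), " samples x ", ncol(x$data),
      " channels @ ", x$rate, " Hz, ", nrow(x$events), " events",
      if (x$preprocessed) " (preprocessed)", "\n", sep = "")
  invisible(x)
}

#' Preprocess an EEG session
#'
#' Per channel: subtract the mean of the resting-baseline segment, remove the
#' linear trend, and band-pass filter to `band` with zero phase. The band-pass
#' is realized as a cascade of a 2nd-order Butterworth high-pass at the lower
#' edge and a 4th-order Butterworth low-pass at the upper edge, each applied
#' forward-backward (`signal::filtfilt`); the cascade keeps the very low
#' high-pass corner (0.1 Hz at 256 Hz sampling) numerically well conditioned.
#' The sampling rate is unchanged.
#'
#' @param session An `eeg_session` with a non-empty resting segment.
#' @param band Passband in Hz, default `c(0.1, 56)`.
#' @return The session with filtered data and `preprocessed = TRUE`.
#' @export
preprocess_eeg <- function(session, band = c(0.1, 56)) {
  stopifnot(inherits(session, "eeg_session"))
  if (is.null(session$resting)) {
    abort("session has no resting segment; baseline correction impossible")
  }
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            band[2] < session$rate / 2)
  rest <- session$resting[1]:session$resting[2]
  n <- nrow(session$data)
  tt <- seq_len(n)
  tt_c <- tt - mean(tt)
  denom <- sum(tt_c^2)
  hp <- signal::butter(2, band[1] / (session$rate / 2), type = "high")
  lp <- signal::butter(4, band[2] / (session$rate / 2), type = "low")
  out <- vapply(seq_len(ncol(session$data)), function(e) {
    x <- session$data[, e]
    x <- x - mean(x[rest])
    x <- x - mean(x) - tt_c * sum(tt_c * x) / denom   # linear detrend
    x <- signal::filtfilt(hp, x)
    signal::filtfilt(lp, x)
  }, numeric(n))
  colnames(out) <- colnames(session$data)
  session$data <- out
  session$preprocessed <- TRUE
  session
}

#' Sliding analysis windows over an epoch
#'
#' Windows of `width_ms` advance by `width_ms - overlap_ms`, starting at the
#' epoch's first sample, for as long as a full window fits:
#' `count = floor((epoch - width) / step) + 1`. With the default 500 ms width
#' and 375 ms overlap on a 2 s epoch at 256 Hz this yields 13 windows, i.e.
#' 13 spectral features per electrode.
#'
#' @param epoch_samples Number of samples in the epoch.
#' @param rate Sampling rate (Hz).
#' @param width_ms Window width (ms).
#' @param overlap_ms Overlap between consecutive windows (ms); must be smaller
#'   than the width.
#' @return A tibble with columns `window`, `start`, `end` (1-based, inclusive).
#' @examples
#' nrow(sliding_windows(512, 256))  # 13
#' @export
sliding_windows <- function(epoch_samples, rate, width_ms = 500,
                            overlap_ms = 375) {
  stopifnot(is_count(epoch_samples), is_number(rate), rate > 0)
  width <- round(width_ms / 1000 * rate)
  overlap <- round(overlap_ms / 1000 * rate)
  if (width <= overlap) abort("window width must exceed the overlap")
  if (width < 1) abort("window width must be at least one sample")
  if (epoch_samples < width) abort("epoch is shorter than one window")
  step <- width - overlap
  n <- (epoch_samples - width) %/% step + 1L
  start <- 1L + (seq_len(n) - 1L) * step
  tibble(window = seq_len(n), start = start, end = start + width - 1L)
}

# Trapezoid quadrature weights over [band[1], band[2]] for values sampled at
# `freqs` (uniform grid), with linear interpolation at the band edges.
# Returns w such that w %*% psd approximates the band integral.
trapz_weights <- function(freqs, band) {
  lo <- band[1]; hi <- band[2]
  nf <- length(freqs)
  edge_coef <- function(f) {
    # linear interpolation coefficients of psd at frequency f
    k <- findInterval(f, freqs)
    k <- min(max(k, 1L), nf - 1L)
    t <- (f - freqs[k]) / (freqs[k + 1] - freqs[k])
    c(k = k, a = 1 - t, b = t)
  }
  inside <- which(freqs > lo & freqs < hi)
  nodes_f <- c(lo, freqs[inside], hi)
  # node values as sparse linear combinations of psd bins
  n_nodes <- length(nodes_f)
  idx <- matrix(0L, n_nodes, 2)
  cf <- matrix(0, n_nodes, 2)
  e1 <- edge_coef(lo)
  idx[1, ] <- c(e1["k"], e1["k"] + 1L); cf[1, ] <- e1[c("a", "b")]
  if (length(inside)) {
    idx[1 + seq_along(inside), 1] <- inside
    cf[1 + seq_along(inside), 1] <- 1
  }
  e2 <- edge_coef(hi)
  idx[n_nodes, ] <- c(e2["k"], e2["k"] + 1L); cf[n_nodes, ] <- e2[c("a", "b")]
  w <- numeric(nf)
  if (n_nodes >= 2) {
    panel <- diff(nodes_f)
    node_w <- c(panel, 0) / 2 + c(0, panel) / 2   # trapezoid node weights
    for (i in seq_len(n_nodes)) {
      for (j in 1:2) {
        if (idx[i, j] >= 1 && idx[i, j] <= nf && cf[i, j] != 0) {
          w[idx[i, j]] <- w[idx[i, j]] + node_w[i] * cf[i, j]
        }
      }
    }
  }
  w
}

#' Band-integrated spectral power of a window
#'
#' Estimates the one-sided power spectral density of the window with a
#' Hann-tapered periodogram and integrates it over `band` by the trapezoid
#' rule (band edges linearly interpolated between frequency bins). With
#' `normalize = TRUE` (default) the integral is divided by the band width,
#' giving the band-average PSD in uV^2/Hz; with `normalize = FALSE` the raw
#' integral (uV^2) is returned.
#'
#' @param x Numeric vector (one window of one channel, uV), or a
#'   samples x channels matrix for the vectorized form.
#' @param rate Sampling rate (Hz).
#' @param band Frequency interval in Hz within `[0, rate/2]`.
#' @param normalize Divide by band width (default `TRUE`).
#' @return A scalar (vector input) or one value per column (matrix input).
#' @examples
#' x <- sin(2 * pi * 10 * (0:127) / 256)
#' band_power(x, 256, c(8, 12), normalize = FALSE)  # ~ 0.5
#' @export
band_power <- function(x, rate, band, normalize = TRUE) {
  if (is.matrix(x)) return(band_power_mat(x, rate, band, normalize))
  as.numeric(band_power_mat(matrix(x, ncol = 1), rate, band, normalize))
}

band_power_mat <- function(X, rate, band, normalize = TRUE) {
  n <- nrow(X)
  if (is.null(n) || n < 2) abort("window must contain at least 2 samples")
  stopifnot(length(band) == 2, band[1] < band[2])
  if (band[1] < 0 || band[2] > rate / 2) {
    abort("band must lie within [0, rate/2]")
  }
  h <- hann_taper(n)
  Xf <- stats::mvfft(X * h)
  nfreq <- n %/% 2 + 1L
  P <- Mod(Xf[seq_len(nfreq), , drop = FALSE])^2 / (rate * sum(h^2))
  # one-sided: double everything except DC (and Nyquist when n is even)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nfreq] <- 1
  P <- P * dbl
  freqs <- (seq_len(nfreq) - 1) * rate / n
  w <- trapz_weights(freqs, band)
  out <- as.numeric(w %*% P)
  if (normalize) out <- out / (band[2] - band[1])
  out
}

#' Extract windowed band-power features for every trial
#'
#' For each non-excluded trial, cuts the post-stimulus epoch and computes one
#' band-power feature per electrode per sliding window. Features are laid out
#' electrode-major (electrode 1's windows first). With the default settings
#' (2 s epoch, 500 ms windows, 375 ms overlap, 32 electrodes) each trial
#' yields 32 x 13 = 416 features.
#'
#' @param session An `eeg_session` (normally preprocessed first with
#'   [preprocess_eeg()]).
#' @param epoch_s Post-stimulus epoch length (s).
#' @param band Frequency band of the feature (Hz).
#' @param window_ms,overlap_ms Sliding-window geometry (ms).
#' @param normalize Divide band integrals by band width (see [band_power()]).
#' @param log_power Return `log10` of the (positive) power features.
#' @return An object of class `feature_matrix`: list with `X`
#'   (trials x features), `provenance` (one row per feature: channel, window,
#'   band), `band`, `trial_index`, and `reduction` (`NULL` until a reducer is
#'   applied).
#' @export
extract_features <- function(session, epoch_s = 2, band = c(0.1, 56),
                             window_ms = 500, overlap_ms = 375,
                             normalize = TRUE, log_power = FALSE) {
  stopifnot(inherits(session, "eeg_session"))
  rate <- session$rate
  E <- round(epoch_s * rate)
  wins <- sliding_windows(E, rate, width_ms = window_ms,
                          overlap_ms = overlap_ms)
  ev <- dplyr::filter(session$events, !.data$excluded)
  onset <- round(ev$cue_on_s * rate) + 1L
  over <- onset + E - 1L > nrow(session$data)
  if (any(over)) {
    abort(paste0("epoch extends past end of recording for trial(s): ",
                 paste(ev$trial_id[over], collapse = ", ")))
  }
  n_ch <- ncol(session$data)
  n_win <- nrow(wins)
  X <- matrix(0, nrow(ev), n_win * n_ch)
  for (i in seq_along(onset)) {
    ep <- session$data[onset[i]:(onset[i] + E - 1L), , drop = FALSE]
    bp <- vapply(seq_len(n_win), function(w) {
      band_power_mat(ep[wins$start[w]:wins$end[w], , drop = FALSE],
                     rate, band, normalize)
    }, numeric(n_ch))                   # n_ch x n_win
    X[i, ] <- as.numeric(t(bp))         # electrode-major
  }
  if (log_power) X <- log10(pmax(X, .Machine$double.xmin))
  prov <- tibble(
    column = seq_len(n_win * n_ch),
    channel = rep(colnames(session$data), each = n_win),
    window = rep(wins$window, n_ch),
    band_lo = band[1], band_hi = band[2]
  )
  new_feature_matrix(X, prov, band,
                     trial_index = ev[, c("trial_id", "grasp_type")],
                     settings = list(epoch_s = epoch_s, window_ms = window_ms,
                                     overlap_ms = overlap_ms,
                                     normalize = normalize,
                                     log_power = log_power))
}

new_feature_matrix <- function(X, provenance, band, trial_index,
                               settings = list(), reduction = NULL) {
  stopifnot(nrow(provenance) == ncol(X), nrow(trial_index) == nrow(X))
  structure(list(X = X, provenance = as_tibble(provenance), band = band,
                 trial_index = as_tibble(trial_index), settings = settings,
                 reduction = reduction),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$X), " trials x ", ncol(x$X), " features, ",
      "band ", x$band[1], "-", x$band[2], " Hz",
      if (!is.null(x$reduction)) " (PCA-reduced)", "\n", sep = "")
  invisible(x)
}

#' Feature matrix for a whole cohort
#'
#' Preprocesses (optionally) and extracts features for every subject, stacking
#' them with the subject id in the trial index.
#'
#' @param cohort A `grasp_cohort`.
#' @param preprocess Run [preprocess_eeg()] on each session first.
#' @inheritParams extract_features
#' @return A `feature_matrix` with `subject` in its trial index.
#' @export
cohort_features <- function(cohort, preprocess = TRUE, epoch_s = NULL,
                            band = c(0.1, 56), window_ms = 500,
                            overlap_ms = 375, normalize = TRUE,
                            log_power = FALSE) {
  stopifnot(inherits(cohort, "grasp_cohort"))
  epoch_s <- epoch_s %||% cohort$protocol$epoch_s
  parts <- purrr::imap(cohort$subjects, function(s, i) {
    ses <- if (preprocess) preprocess_eeg(s$eeg) else s$eeg
    fm <- extract_features(ses, epoch_s = epoch_s, band = band,
                           window_ms = window_ms, overlap_ms = overlap_ms,
                           normalize = normalize, log_power = log_power)
    fm$trial_index$subject <- i
    fm
  })
  X <- do.call(rbind, lapply(parts, `[[`, "X"))
  ti <- dplyr::bind_rows(lapply(parts, `[[`, "trial_index"))
  new_feature_matrix(X, parts[[1]]$provenance, band, ti,
                     settings = parts[[1]]$settings)
}

# Subset rows of a feature_matrix.
fm_subset <- function(fm, rows) {
  new_feature_matrix(fm$X[rows, , drop = FALSE], fm$provenance, fm$band,
                     fm$trial_index[rows, , drop = FALSE], fm$settings,
                     fm$reduction)
}

# Subset feature columns (e.g. an electrode neighborhood).
fm_select_channels <- function(fm, channels) {
  cols <- fm$provenance$column[fm$provenance$channel %in% channels]
  if (length(cols) == 0) abort("no features for the requested channels")
  prov <- fm$provenance[cols, , drop = FALSE]
  prov$column <- seq_len(nrow(prov))
  new_feature_matrix(fm$X[, cols, drop = FALSE], prov, fm$band,
                     fm$trial_index, fm$settings)
}

#' Fit a PCA feature reducer on training rows
#'
#' Principal component analysis across the (mean-centered) feature columns,
#' retaining the smallest number of top-ranked components whose cumulative
#' explained variance reaches `rule` (a fraction in (0, 1)), or exactly `rule`
#' components when `rule` is an integer count. The fitted means and loadings
#' are stored so held-out subjects are projected with training-fit parameters
#' only; `fit_rows` records which rows the fit saw, which the cross-validation
#' loop uses as a leakage guard.
#'
#' @param fm A `feature_matrix`.
#' @param rows Row indices to fit on (training trials). Default: all rows.
#' @param rule Retained-variance fraction in (0, 1) or integer component count.
#' @return An object of class `feature_reducer`.
#' @export
fit_feature_reducer <- function(fm, rows = NULL, rule = 0.9) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!is.null(fm$reduction)) abort("feature matrix is already reduced")
  rows <- rows %||% seq_len(nrow(fm$X))
  Xtr <- fm$X[rows, , drop = FALSE]
  pr <- prcomp(Xtr, center = TRUE, scale. = FALSE)
  var_frac <- pr$sdev^2 / sum(pr$sdev^2)
  if (is_count(rule)) {
    k <- min(as.integer(rule), ncol(pr$rotation))
  } else if (is_number(rule) && rule > 0 && rule < 1) {
    k <- which(cumsum(var_frac) >= rule - 1e-12)[1]
  } else {
    abort("rule must be a variance fraction in (0,1) or a component count")
  }
  structure(list(center = pr$center,
                 loadings = pr$rotation[, seq_len(k), drop = FALSE],
                 k = k, rule = rule,
                 explained = cumsum(var_frac)[k],
                 fit_rows = rows, p = ncol(fm$X)),
            class = "feature_reducer")
}

#' Apply a fitted feature reducer
#'
#' Projects features onto the training-fit principal components. Applying an
#' object that is not a fitted `feature_reducer` is an error (the "unfitted
#' reducer" state error of the pipeline).
#'
#' @param fm A `feature_matrix` with the same feature columns the reducer was
#'   fit on.
#' @param reducer A `feature_reducer` from [fit_feature_reducer()].
#' @return A reduced `feature_matrix` whose `reduction` field stores the
#'   reducer.
#' @export
apply_feature_reducer <- function(fm, reducer) {
  if (!inherits(reducer, "feature_reducer")) {
    abort("reducer has not been fitted (expected a feature_reducer object)")
  }
  stopifnot(inherits(fm, "feature_matrix"))
  if (ncol(fm$X) != reducer$p) {
    abort("feature count does not match the fitted reducer")
  }
  Xr <- sweep(fm$X, 2, reducer$center) %*% reducer$loadings
  prov <- tibble(column = seq_len(reducer$k),
                 channel = NA_character_,
                 window = NA_integer_,
                 band_lo = fm$band[1], band_hi = fm$band[2],
                 component = seq_len(reducer$k))
  new_feature_matrix(Xr, prov, fm$band, fm$trial_index, fm$settings,
                     reduction = reducer)
}

#' Canonical EEG frequency bands
#'
#' Delta 0.1-4, theta 4-8, mu 8-12, beta 18-30 and gamma 30-56 Hz. Mu and
#' beta follow the sensorimotor-rhythm convention; delta's lower edge and
#' gamma's upper edge are capped by the 0.1-56 Hz analysis filter. The
#' 12-18 Hz interval belongs to no named band and is covered only by the
#' full-band feature set.
#'
#' @return Named list of length-2 numeric vectors (Hz).
#' @export
eeg_bands <- function() {
  list(delta = c(0.1, 4), theta = c(4, 8), mu = c(8, 12),
       beta = c(18, 30), gamma = c(30, 56))
}
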
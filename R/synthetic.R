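#' Recording protocol constants
#'
#' Bundles the acquisition constants used by the synthetic cohort generator and
#' the segmentation code: six grasp types repeated 30 times each (180 cue
#' events per subject), glove kinematics at 125 Hz, 32-channel EEG at 256 Hz,
#' and a 2 s post-stimulus epoch. `rest_s` is an initial eyes-open resting
#' stretch used for baseline correction; `gap_s` is the inter-trial interval
#' during which the hand returns to the flat calibration posture.
#'
#' @param n_grasps Number of grasp types.
#' @param n_reps Repetitions per grasp type.
#' @param kin_rate Joint-angle sampling rate (Hz).
#' @param eeg_rate EEG sampling rate (Hz).
#' @param epoch_s Post-stimulus epoch length (seconds).
#' @param rest_s Initial resting-baseline length (seconds).
#' @param gap_s Inter-trial gap (seconds).
#' @return A list of class `grasp_protocol`.
#' @export
grasp_protocol <- function(n_grasps = 6, n_reps = 30, kin_rate = 125,
                           eeg_rate = 256, epoch_s = 2, rest_s = 4,
                           gap_s = 1) {
  stopifnot(is_count(n_grasps), is_count(n_reps),
            is_number(kin_rate), kin_rate > 0,
            is_number(eeg_rate), eeg_rate > 0,
            is_number(epoch_s), epoch_s > 0,
            is_number(rest_s), rest_s >= 0,
            is_number(gap_s), gap_s > 0)
  # cue times must land on both sampling grids
  for (x in c(epoch_s, rest_s, gap_s)) {
    if (abs(x * kin_rate - round(x * kin_rate)) > 1e-9 ||
        abs(x * eeg_rate - round(x * eeg_rate)) > 1e-9) {
      abort("protocol durations must be whole numbers of samples at both rates")
    }
  }
  structure(list(n_grasps = n_grasps, n_reps = n_reps, kin_rate = kin_rate,
                 eeg_rate = eeg_rate, epoch_s = epoch_s, rest_s = rest_s,
                 gap_s = gap_s),
            class = "grasp_protocol")
}

#' Default joint order of the 10 measured hand joints
#'
#' Metacarpophalangeal (MCP) joints of thumb and four fingers, the thumb
#' interphalangeal (IP) joint and the proximal interphalangeal (PIP) joints of
#' the four fingers, ordered thumb, index, middle, ring, pinky.
#' @return Character vector of length 10.
#' @export
hand_joint_labels <- function() {
  c("TMCP", "TIP", "IMCP", "IPIP", "MMCP",
    "MPIP", "RMCP", "RPIP", "PMCP", "PPIP")
}

# Smooth random curves: one row per synergy, joint-major layout
# (n_joints blocks of epoch_samples each), built from a few random sinusoids.
smooth_random_curves <- function(n_syn, n_joints, epoch_samples) {
  t_rel <- (0:(epoch_samples - 1)) / epoch_samples
  raw <- matrix(0, n_syn, n_joints * epoch_samples)
  for (i in seq_len(n_syn)) {
    for (j in seq_len(n_joints)) {
      ncomp <- 3L
      f <- runif(ncomp, 0.5, 3)
      a <- rnorm(ncomp)
      ph <- runif(ncomp, 0, 2 * pi)
      curve <- colSums(a * sin(outer(2 * pi * f, t_rel) + ph))
      raw[i, (j - 1) * epoch_samples + seq_len(epoch_samples)] <- curve
    }
  }
  raw
}

# Orthonormalize the rows of M (returns a matrix with orthonormal rows
# spanning the same row space). Errors if M is row-rank deficient.
orthonormal_rows <- function(M) {
  qrM <- qr(t(M))
  if (qrM$rank < nrow(M)) {
    abort("requested number of synergies exceeds the matrix rank")
  }
  t(qr.Q(qrM))
}

# Post-stimulus power envelope: brief desynchronization (power dip) followed
# by a synchronization rebound, in units of the coupling drive.
erd_ers_envelope <- function(epoch_samples, rate) {
  t <- (0:(epoch_samples - 1)) / rate
  T <- epoch_samples / rate
  -0.6 * exp(-((t - 0.15 * T) / (0.06 * T))^2) +
    exp(-((t - 0.55 * T) / (0.175 * T))^2)
}

# Linear operator Phi (n_windows x epoch_samples) mapping the carrier's
# instantaneous power q(t) to the band-integrated windowed PSD features the
# extractor computes: for x(t) = sqrt(q(t)) sin(2 pi f0 t / fs), the one-sided
# periodogram integral over a band containing all signal energy equals
# sum_t h^2 q s^2 / sum_t h^2 (Parseval), optionally divided by bandwidth.
window_power_operator <- function(epoch_samples, rate, window_ms = 500,
                                  overlap_ms = 375, band = c(0.1, 56),
                                  normalize = TRUE, carrier_hz = 10) {
  wins <- sliding_windows(epoch_samples, rate, window_ms, overlap_ms)
  width <- wins$end[1] - wins$start[1] + 1L
  h2 <- hann_taper(width)^2
  s <- sin(2 * pi * carrier_hz * (0:(epoch_samples - 1)) / rate)
  Phi <- matrix(0, nrow(wins), epoch_samples)
  for (w in seq_len(nrow(wins))) {
    idx <- wins$start[w]:wins$end[w]
    Phi[w, idx] <- h2 * s[idx]^2 / sum(h2)
  }
  if (normalize) Phi <- Phi / (band[2] - band[1])
  pinv <- t(Phi) %*% solve(Phi %*% t(Phi))
  list(Phi = Phi, pinv = pinv, windows = wins, carrier = s,
       carrier_hz = carrier_hz, band = band, normalize = normalize)
}

#' Create the generative ground truth of a synthetic cohort
#'
#' Builds the hidden structure every synthetic subject shares: a set of
#' orthonormal spatiotemporal synergies (smooth random multi-joint velocity
#' curves), per-grasp-type synergy-weight distributions whose leading
#' components dominate with a stated variance profile, and a sparse
#' non-negative coupling that concentrates each synergy's EEG band-power
#' encoding on a contiguous electrode neighborhood.
#'
#' Movement generation follows the synergy model: a trial's velocity epoch is
#' the weight vector times the synergy matrix plus Gaussian noise. The EEG side
#' modulates a mu-rhythm carrier so that windowed band-power features are
#' `baseline + coupling %*% c` plus feature noise (see
#' [feature_coupling()]).
#'
#' @param n_syn Number of ground-truth synergies.
#' @param n_joints Number of hand joints.
#' @param epoch_samples Kinematic samples per epoch (epoch length x glove rate).
#' @param n_grasps Number of grasp types.
#' @param seed Integer seed; the ground truth is a deterministic function of it.
#' @param variance_profile Fractions of signal variance carried by each synergy
#'   (length `n_syn`, summing to 1). The default six-synergy profile is chosen
#'   so that, with the default kinematic noise, the cumulative variance of the
#'   velocity matrix crosses 85% at exactly six components.
#' @param signal_energy Expected squared norm of a trial's weight vector
#'   (deg^2/s^2 summed over the flattened epoch); sets overall movement scale.
#' @param within_frac Fraction of each synergy's variance that is trial-to-trial
#'   (within grasp type) rather than between grasp-type means.
#' @param noise_sd_kin Additive kinematic velocity noise sd (deg/s).
#' @param noise_sd_feat Additive EEG feature noise sd, in feature units
#'   (band-averaged PSD, uV^2/Hz).
#' @param coupling_strength Peak band-power drive of one synergy at its center
#'   electrode (uV^2 of instantaneous carrier power per weight rms).
#' @param carrier_hz Carrier frequency of the encoded rhythm (Hz; on an FFT bin
#'   of the analysis window so that Hann leakage stays in band).
#' @param montage Electrode montage tibble (`channel`, `x`, `y`).
#' @param coupling_radius Scalp radius beyond which a synergy's coupling is
#'   exactly zero (sparsity of the planted encoding).
#' @param synergy_jitter Optional per-subject synergy perturbation magnitude
#'   (0 = all subjects share identical synergies).
#' @return An object of class `grasp_ground_truth`.
#' @examples
#' gt <- make_ground_truth(n_syn = 2, n_joints = 3, epoch_samples = 50, seed = 1)
#' tcrossprod(gt$synergies) # ~ identity
#' @export
make_ground_truth <- function(n_syn = 6, n_joints = 10, epoch_samples = 250,
                              n_grasps = 6, seed = 1,
                              variance_profile = NULL,
                              signal_energy = 1e6,
                              within_frac = 0.5,
                              noise_sd_kin = 6,
                              noise_sd_feat = 0.05,
                              coupling_strength = 60,
                              carrier_hz = 10,
                              montage = gamma_montage_32(),
                              coupling_radius = 0.45,
                              synergy_jitter = 0) {
  if (!is_count(n_syn)) abort("n_syn must be a positive integer")
  if (n_syn > n_joints * epoch_samples) {
    abort("n_syn may not exceed n_joints * epoch_samples")
  }
  stopifnot(is_count(n_joints), is_count(epoch_samples), is_count(n_grasps),
            within_frac >= 0, within_frac <= 1,
            noise_sd_kin >= 0, noise_sd_feat >= 0)
  validate_montage(montage)
  if (is.null(variance_profile)) {
    variance_profile <- if (n_syn == 6) {
      c(0.25, 0.185, 0.155, 0.13, 0.12, 0.11) / 0.95
    } else {
      p <- 0.75^(0:(n_syn - 1)); p / sum(p)
    }
  }
  stopifnot(length(variance_profile) == n_syn, all(variance_profile > 0))
  variance_profile <- variance_profile / sum(variance_profile)

  set.seed(derive_seed(seed, 0L))
  synergies <- orthonormal_rows(
    smooth_random_curves(n_syn, n_joints, epoch_samples))

  energies <- variance_profile * signal_energy
  weight_sds <- sqrt(within_frac * energies)
  # Grasp-type mean weight vectors. When enough grasp types exist, the mean
  # matrix columns are orthogonalized so the weights' second-moment matrix is
  # exactly diag(energies) and the velocity variance spectrum follows the
  # requested profile; otherwise only the per-synergy scale is normalized.
  mu_raw <- matrix(rnorm(n_grasps * n_syn), n_grasps, n_syn)
  target_ms <- (1 - within_frac) * energies
  if (n_grasps >= n_syn) {
    Q <- qr.Q(qr(mu_raw))
    weight_means <- sweep(Q, 2, sqrt(n_grasps * target_ms), `*`)
  } else {
    weight_means <- vapply(seq_len(n_syn), function(j) {
      ms <- mean(mu_raw[, j]^2)
      if (ms == 0) ms <- 1
      mu_raw[, j] * sqrt(target_ms[j] / ms)
    }, numeric(n_grasps))
    weight_means <- matrix(weight_means, n_grasps, n_syn)
  }

  # coupling: gaussian falloff around a center electrode, hard-zero beyond
  # coupling_radius, scaled so the center drive is coupling_strength at the
  # synergy's rms weight
  centers <- coupling_centers(montage, n_syn)
  xy <- as.matrix(montage[, c("x", "y")])
  gain <- matrix(0, nrow(montage), n_syn,
                 dimnames = list(montage$channel, NULL))
  for (j in seq_len(n_syn)) {
    ci <- match(centers[j], montage$channel)
    d2 <- (xy[, 1] - xy[ci, 1])^2 + (xy[, 2] - xy[ci, 2])^2
    prof <- exp(-d2 / (2 * 0.12^2))
    prof[sqrt(d2) > coupling_radius] <- 0
    gain[, j] <- prof / prof[ci] * coupling_strength / sqrt(energies[j])
  }
  drive_max <- as.numeric(
    gain %*% (apply(abs(weight_means), 2, max) + 4 * weight_sds))
  alpha <- 20 + 0.7 * drive_max

  structure(list(
    synergies = synergies,
    n_syn = n_syn, n_joints = n_joints, epoch_samples = epoch_samples,
    n_grasps = n_grasps,
    weight_means = weight_means,
    weight_sds = weight_sds,
    energies = energies,
    coupling = list(gain = gain, alpha = alpha, centers = centers,
                    carrier_hz = carrier_hz, montage = montage,
                    window_ms = 500, overlap_ms = 375,
                    band = c(0.1, 56), normalize = TRUE),
    noise_sd_kin = noise_sd_kin,
    noise_sd_feat = noise_sd_feat,
    synergy_jitter = synergy_jitter,
    seed = seed
  ), class = "grasp_ground_truth")
}

# Pick spatially spread coupling centers over the sensorimotor strip by
# greedy max-min-distance selection (seeded at C3, the contralateral hand
# area for right-handed subjects). Spread keeps the planted per-synergy
# encodings identifiable from one another.
coupling_centers <- function(montage, n_syn) {
  strip <- montage$channel[grepl("^(FC|C|CP)", montage$channel)]
  if (length(strip) < n_syn) strip <- montage$channel
  xy <- as.matrix(montage[match(strip, montage$channel), c("x", "y")])
  first <- if ("C3" %in% strip) match("C3", strip) else 1L
  chosen <- first
  while (length(chosen) < n_syn) {
    d <- vapply(seq_along(strip), function(i) {
      min(sqrt((xy[chosen, 1] - xy[i, 1])^2 + (xy[chosen, 2] - xy[i, 2])^2))
    }, 0)
    d[chosen] <- -Inf
    chosen <- c(chosen, which.max(d))
  }
  strip[chosen]
}

#' Expected feature-level encoding of the ground truth
#'
#' Returns the affine map from a trial's synergy-weight vector to the expected
#' windowed band-power feature vector of that trial, in the electrode-major
#' feature order used by [extract_features()]: features of a trial equal
#' `baseline + coupling %*% c` (+ feature noise). With zero feature noise the
#' identity is exact up to spectral leakage outside the analysis band.
#'
#' @param gt A `grasp_ground_truth`.
#' @param protocol A `grasp_protocol` (sets epoch length and EEG rate).
#' @return List with `baseline` (length 13 x n_electrodes) and `coupling`
#'   (features x n_syn matrix).
#' @export
feature_coupling <- function(gt, protocol = grasp_protocol()) {
  cp <- gt$coupling
  E <- round(protocol$epoch_s * protocol$eeg_rate)
  wp <- window_power_operator(E, protocol$eeg_rate, cp$window_ms,
                              cp$overlap_ms, cp$band, cp$normalize,
                              cp$carrier_hz)
  env <- erd_ers_envelope(E, protocol$eeg_rate)
  phi_env <- as.numeric(wp$Phi %*% env)   # n_windows
  phi_one <- as.numeric(wp$Phi %*% rep(1, E))
  n_ch <- nrow(cp$gain)
  n_win <- length(phi_env)
  # electrode-major: electrode 1 windows 1..13, electrode 2 windows 1..13, ...
  baseline <- as.numeric(outer(phi_one, cp$alpha))    # win fastest
  baseline <- as.numeric(matrix(baseline, n_win, n_ch))
  M <- matrix(0, n_win * n_ch, gt$n_syn)
  for (e in seq_len(n_ch)) {
    rows <- (e - 1) * n_win + seq_len(n_win)
    M[rows, ] <- outer(phi_env, cp$gain[e, ])
  }
  list(baseline = baseline, coupling = M, windows = wp$windows)
}

#' Generate one synthetic subject
#'
#' Draws the subject's trial schedule and per-trial synergy weights from the
#' shared ground truth, integrates the synergy-generated velocity epochs into
#' joint-angle recordings (each trial starting from the flat 0 deg calibration
#' posture), and synthesizes EEG whose post-stimulus band power encodes the
#' weights: within each epoch a mu-band carrier is amplitude-modulated so its
#' windowed band-power features equal `baseline + coupling %*% c` plus Gaussian
#' feature noise, with a brief post-stimulus power dip followed by a rebound.
#' Between trials and during the initial resting stretch the EEG is 1/f-like
#' background plus a resting alpha rhythm.
#'
#' @param gt A `grasp_ground_truth`.
#' @param protocol A `grasp_protocol`.
#' @param subject_seed Integer seed for this subject's substream.
#' @param exclusion_rate Probability that a trial is flagged as
#'   artifact-excluded (data still generated; downstream stages skip it).
#' @return List with elements `kinematics` (a `kin_session`), `eeg` (an
#'   `eeg_session`) and `weights` (trials x n_syn matrix of ground-truth
#'   synergy weights).
#' @export
generate_subject <- function(gt, protocol = grasp_protocol(), subject_seed = 1,
                             exclusion_rate = 0) {
  stopifnot(inherits(gt, "grasp_ground_truth"),
            inherits(protocol, "grasp_protocol"),
            exclusion_rate >= 0, exclusion_rate < 1)
  if (round(protocol$epoch_s * protocol$kin_rate) != gt$epoch_samples) {
    abort("protocol epoch length does not match ground-truth epoch_samples")
  }
  if (protocol$n_grasps != gt$n_grasps) {
    abort("protocol n_grasps does not match ground truth")
  }
  set.seed(subject_seed)
  n_trials <- protocol$n_grasps * protocol$n_reps
  grasp <- sample(rep(seq_len(protocol$n_grasps), protocol$n_reps))
  trial_len <- protocol$epoch_s + protocol$gap_s
  cue_on <- protocol$rest_s + (seq_len(n_trials) - 1) * trial_len
  events <- tibble(
    trial_id = seq_len(n_trials),
    grasp_type = grasp,
    cue_on_s = cue_on,
    cue_off_s = cue_on + protocol$epoch_s,
    excluded = runif(n_trials) < exclusion_rate
  )

  S <- gt$synergies
  if (gt$synergy_jitter > 0) {
    pert <- smooth_random_curves(gt$n_syn, gt$n_joints, gt$epoch_samples)
    pert <- pert / sqrt(rowSums(pert^2))
    S <- orthonormal_rows(S + gt$synergy_jitter * pert)
  }

  W <- t(vapply(seq_len(n_trials), function(i) {
    gt$weight_means[grasp[i], ] + rnorm(gt$n_syn) * gt$weight_sds
  }, numeric(gt$n_syn)))
  W <- matrix(W, n_trials, gt$n_syn)

  kin <- synth_kinematics(gt, protocol, events, W, S)
  eeg <- synth_eeg(gt, protocol, events, W)
  list(kinematics = kin, eeg = eeg, weights = W)
}

synth_kinematics <- function(gt, protocol, events, W, S) {
  rate <- protocol$kin_rate
  E <- gt$epoch_samples
  n_samples <- round((protocol$rest_s +
                        nrow(events) * (protocol$epoch_s + protocol$gap_s)) * rate)
  angles <- matrix(0, n_samples, gt$n_joints)
  onset_idx <- round(events$cue_on_s * rate) + 1L
  for (i in seq_len(nrow(events))) {
    v <- matrix(W[i, ] %*% S, E, gt$n_joints)   # joint-major unflatten
    if (gt$noise_sd_kin > 0) {
      v <- v + matrix(rnorm(E * gt$n_joints, 0, gt$noise_sd_kin), E)
    }
    o <- onset_idx[i]
    a <- apply(v / rate, 2, cumsum)
    angles[o + seq_len(E), ] <- a          # angle at cue onset is exactly 0
    # return linearly to the flat posture during the gap
    gap_end <- if (i < nrow(events)) onset_idx[i + 1] else n_samples
    ngap <- gap_end - (o + E)
    if (ngap > 0) {
      frac <- seq(1 - 1 / ngap, 0, length.out = ngap)
      angles[o + E + seq_len(ngap), ] <- outer(frac, a[E, ])
    }
  }
  new_kin_session(angles, rate, events, hand_joint_labels()[seq_len(gt$n_joints)])
}

synth_eeg <- function(gt, protocol, events, W) {
  cp <- gt$coupling
  rate <- protocol$eeg_rate
  E <- round(protocol$epoch_s * rate)
  n_ch <- nrow(cp$gain)
  n_samples <- round((protocol$rest_s +
                        nrow(events) * (protocol$epoch_s + protocol$gap_s)) * rate)
  wp <- window_power_operator(E, rate, cp$window_ms, cp$overlap_ms,
                              cp$band, cp$normalize, cp$carrier_hz)
  env <- erd_ers_envelope(E, rate)

  # Background outside the epochs: AR(1) broadband noise plus a per-channel
  # DC offset, both crossfaded to zero around each epoch so splices are
  # smooth, riding on a resting rhythm that continues the epochs' carrier
  # (same phase, amplitude sqrt(alpha) = the epoch edge amplitude).
  onset_idx <- round(events$cue_on_s * rate) + 1L
  bg_w <- rep(1, n_samples)
  ramp <- 64L
  for (o in onset_idx) {
    bg_w[o:(o + E - 1L)] <- 0
    lo <- max(1L, o - ramp)
    bg_w[lo:(o - 1L)] <- pmin(bg_w[lo:(o - 1L)],
                              rev(seq_len(o - lo)) / (ramp + 1))
    hi <- min(n_samples, o + E - 1L + ramp)
    if (hi >= o + E) {
      bg_w[(o + E):hi] <- pmin(bg_w[(o + E):hi],
                               seq_len(hi - o - E + 1L) / (ramp + 1))
    }
  }
  s_glob <- sin(2 * pi * cp$carrier_hz * (0:(n_samples - 1)) / rate)
  # drift below the analysis band is removed at generation so the broadband
  # background is invariant under the pipeline's own high-pass
  hp_bg <- signal::butter(2, 0.5 / (rate / 2), type = "high")
  data <- vapply(seq_len(n_ch), function(e) {
    ar <- as.numeric(stats::filter(rnorm(n_samples, 0, 1.7), 0.95,
                                   method = "recursive"))
    ar <- signal::filtfilt(hp_bg, ar)
    ar * bg_w + sqrt(cp$alpha[e]) * s_glob
  }, numeric(n_samples))
  n_win <- nrow(wp$windows)
  for (i in seq_len(nrow(events))) {
    drive <- as.numeric(cp$gain %*% W[i, ])
    q <- outer(env, drive) + matrix(cp$alpha, E, n_ch, byrow = TRUE)
    if (gt$noise_sd_feat > 0) {
      eps <- matrix(rnorm(n_win * n_ch, 0, gt$noise_sd_feat), n_win, n_ch)
      q <- q + wp$pinv %*% eps
    }
    rows <- onset_idx[i]:(onset_idx[i] + E - 1L)
    data[rows, ] <- sqrt(pmax(q, 0.25)) * wp$carrier
  }
  new_eeg_session(data, rate, cp$montage, events,
                  resting = c(1L, round(protocol$rest_s * rate)))
}

#' Generate a multi-subject synthetic cohort
#'
#' All subjects share one ground truth (the cross-subject generalizability the
#' decoder exploits is a property of that shared synergy structure); subject
#' data are otherwise independent, generated from per-subject substreams of the
#' cohort seed.
#'
#' @inheritParams generate_subject
#' @param n_subjects Number of subjects (>= 2, so that a train/test subject
#'   split exists).
#' @param seed Integer cohort seed.
#' @return An object of class `grasp_cohort`: list with `subjects` (list of
#'   per-subject lists as returned by [generate_subject()]), `ground_truth`
#'   and `protocol`.
#' @examples
#' gt <- make_ground_truth(n_syn = 2, n_joints = 3, epoch_samples = 50, seed = 1)
#' ch <- generate_cohort(gt, n_subjects = 2,
#'                       protocol = grasp_protocol(n_grasps = 6, n_reps = 2),
#'                       seed = 1)
#' length(ch$subjects)
#' @export
generate_cohort <- function(gt, n_subjects = 10, protocol = grasp_protocol(),
                            seed = 1, exclusion_rate = 0) {
  if (!is_count(n_subjects, min = 2L)) {
    abort("n_subjects must be an integer >= 2 (train/test split impossible otherwise)")
  }
  subjects <- lapply(seq_len(n_subjects), function(i) {
    generate_subject(gt, protocol, derive_seed(seed, i), exclusion_rate)
  })
  structure(list(subjects = subjects, ground_truth = gt, protocol = protocol),
            class = "grasp_cohort")
}

#' @export
print.grasp_cohort <- function(x, ...) {
  p <- x$protocol
  cat("<grasp_cohort> ", length(x$subjects), " subjects, ",
      p$n_grasps, " grasps x ", p$n_reps, " reps, ",
      "kin ", p$kin_rate, " Hz / eeg ", p$eeg_rate, " Hz\n", sep = "")
  invisible(x)
}

#' @export
print.grasp_ground_truth <- function(x, ...) {
  cat("<grasp_ground_truth> ", x$n_syn, " synergies, ", x$n_joints,
      " joints x ", x$epoch_samples, " samples, ", x$n_grasps, " grasp types\n",
      sep = "")
  invisible(x)
}
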
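# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) assign(key, builder(), .fixture_cache)
  .fixture_cache[[key]]
}

# Small, fast protocol: 3 grasps x 4 reps, short rest.
small_protocol <- function(n_reps = 4) {
  grasp_protocol(n_grasps = 3, n_reps = n_reps, rest_s = 2)
}

# Noise-free 3-synergy ground truth over 4 joints.
clean_gt <- function() {
  fixture("clean_gt", function() {
    make_ground_truth(n_syn = 3, n_joints = 4, epoch_samples = 250,
                      n_grasps = 3, seed = 7,
                      noise_sd_kin = 0, noise_sd_feat = 0)
  })
}

# One noise-free subject under the small protocol.
clean_subject <- function() {
  fixture("clean_subject", function() {
    generate_subject(clean_gt(), small_protocol(), subject_seed = 11)
  })
}

# Small noisy cohort (default-style noise, 3 synergies, 2 subjects).
noisy_cohort <- function() {
  fixture("noisy_cohort", function() {
    gt <- make_ground_truth(n_syn = 3, n_joints = 4, epoch_samples = 250,
                            n_grasps = 3, seed = 7,
                            noise_sd_kin = 6, noise_sd_feat = 0.05)
    generate_cohort(gt, n_subjects = 2, protocol = small_protocol(n_reps = 6),
                    seed = 5)
  })
}

# Two full-protocol subjects from the package-default ground truth, with the
# derived feature/velocity matrices (reused by map and selection tests).
default_pair <- function() {
  fixture("default_pair", function() {
    gt <- make_ground_truth(seed = 7)
    cohort <- generate_cohort(gt, n_subjects = 2,
                              protocol = grasp_protocol(), seed = 5)
    list(gt = gt, cohort = cohort,
         features = cohort_features(cohort),
         velocity = cohort_velocity(cohort))
  })
}

# Tiny hand-built EEG session: known deterministic data, two identical trials.
toy_eeg_session <- function(n_ch = 3, rate = 256) {
  mont <- gamma_montage_32()[seq_len(n_ch), ]
  n <- 6 * rate
  t <- (0:(n - 1)) / rate
  data <- vapply(seq_len(n_ch), function(e) {
    sin(2 * pi * 10 * t + e) + 0.5 * sin(2 * pi * 23 * t)
  }, numeric(n))
  ev <- tibble::tibble(trial_id = 1:2, grasp_type = c(1L, 1L),
                       cue_on_s = c(2, 4), cue_off_s = c(4, 6),
                       excluded = FALSE)
  new_eeg_session(data, rate, mont, ev, resting = c(1L, 2L * rate))
}
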
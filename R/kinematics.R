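#' Construct a kinematics session
#'
#' A kinematics session holds one subject's joint-angle time series (degrees)
#' together with its cue-event table and ordered joint labels.
#'
#' @param angles Numeric matrix, samples x joints (degrees).
#' @param rate Sampling rate in Hz.
#' @param events Tibble with columns `trial_id`, `grasp_type`, `cue_on_s`,
#'   `cue_off_s`, `excluded`.
#' @param joint_labels Character vector naming the joint columns in order.
#' @return An object of class `kin_session`.
#' @export
new_kin_session <- function(angles, rate, events,
                            joint_labels = hand_joint_labels()) {
  angles <- as.matrix(angles)
  if (ncol(angles) != length(joint_labels)) {
    abort("number of joint columns must match joint_labels")
  }
  validate_events(events, n_samples = nrow(angles), rate = rate)
  colnames(angles) <- joint_labels
  structure(list(angles = angles, rate = rate, events = as_tibble(events),
                 joint_labels = joint_labels),
            class = "kin_session")
}

validate_events <- function(events, n_samples, rate) {
  need <- c("trial_id", "grasp_type", "cue_on_s", "cue_off_s", "excluded")
  if (!all(need %in% names(events))) {
    abort(paste("events table must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(events) > 0) {
    if (any(diff(events$cue_on_s) <= 0)) {
      abort("cue onsets must be strictly increasing")
    }
    if (any(events$cue_on_s < 0) ||
        any(events$cue_off_s * rate > n_samples)) {
      abort("event times fall outside the recording span")
    }
  }
  invisible(events)
}

#' @export
print.kin_session <- function(x, ...) {
  cat("<kin_session> ", nrow(x$angles), " samples x ", ncol(x$angles),
      " joints @ ", x$rate, " Hz, ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Joint angular velocities by forward difference
#'
#' First-order forward difference of the joint angles scaled by the sampling
#' rate: `v[t] = (a[t+1] - a[t]) * rate`, in deg/s. The output has one row
#' fewer than the input.
#'
#' @param angles Numeric vector or matrix of joint angles (degrees).
#' @param rate Sampling rate (Hz).
#' @return Velocity vector/matrix in deg/s, length (rows) = input - 1.
#' @examples
#' angular_velocity(c(0, 1, 3), rate = 125)  # 125, 250
#' @export
angular_velocity <- function(angles, rate) {
  stopifnot(is_number(rate), rate > 0)
  if (is.vector(angles)) angles <- matrix(angles, ncol = 1)
  if (nrow(angles) < 2) abort("at least 2 samples are required to differentiate")
  v <- diff(angles) * rate
  if (ncol(v) == 1 && is.null(colnames(v))) as.numeric(v) else v
}

#' Segment cue-aligned velocity epochs
#'
#' Differentiates the session's joint angles and cuts one velocity block per
#' non-excluded trial, starting at the cue-onset sample (0-based half-open
#' window `[onset, onset + epoch)`).
#'
#' @param session A `kin_session`.
#' @param epoch_s Epoch length in seconds (> 0).
#' @return A list of `[epoch_samples x n_joints]` velocity matrices (deg/s),
#'   with a `trial_info` attribute (tibble of trial_id / grasp_type).
#' @export
segment_trials <- function(session, epoch_s) {
  stopifnot(inherits(session, "kin_session"))
  if (!is_number(epoch_s) || epoch_s <= 0) {
    abort("epoch_s must be a positive number of seconds")
  }
  rate <- session$rate
  E <- round(epoch_s * rate)
  vel <- diff(session$angles) * rate
  ev <- dplyr::filter(session$events, !.data$excluded)
  onset <- round(ev$cue_on_s * rate) + 1L
  over <- onset + E - 1L > nrow(vel)
  if (any(over)) {
    abort(paste0("epoch extends past end of recording for trial(s): ",
                 paste(ev$trial_id[over], collapse = ", ")))
  }
  epochs <- lapply(seq_along(onset), function(i) {
    vel[onset[i]:(onset[i] + E - 1L), , drop = FALSE]
  })
  attr(epochs, "trial_info") <- ev[, c("trial_id", "grasp_type")]
  attr(epochs, "joint_labels") <- session$joint_labels
  epochs
}

#' Flatten an epoch to one row, joint-major
#'
#' The row layout concatenates joint 1's full epoch, then joint 2's, and so
#' on, so a length-`n_joints * epoch_samples` row slices cleanly per joint.
#' `unflatten_epoch()` is the exact inverse.
#'
#' @param epoch `[epoch_samples x n_joints]` matrix.
#' @return Numeric vector of length `epoch_samples * n_joints`.
#' @export
flatten_epoch <- function(epoch) as.numeric(as.matrix(epoch))

#' @rdname flatten_epoch
#' @param row Flattened numeric vector.
#' @param epoch_samples Number of samples per joint.
#' @export
unflatten_epoch <- function(row, epoch_samples) {
  if (length(row) %% epoch_samples != 0) {
    abort("row length is not a multiple of epoch_samples")
  }
  matrix(row, nrow = epoch_samples)
}

#' Assemble the velocity matrix V
#'
#' Stacks flattened velocity epochs into the trials x (joints * samples)
#' matrix that synergy extraction decomposes. Each row is one trial's epoch in
#' joint-major order.
#'
#' @param epochs List of equally-shaped `[epoch_samples x n_joints]` matrices
#'   (as from [segment_trials()]).
#' @param trial_index Optional tibble (one row per epoch) carried along to
#'   identify rows; defaults to the `trial_info` attribute of `epochs`.
#' @return An object of class `velocity_matrix`: list with `V`, `layout`
#'   (joint labels, epoch_samples, n_joints) and `trial_index`.
#' @export
build_velocity_matrix <- function(epochs, trial_index = NULL) {
  if (length(epochs) == 0) abort("no epochs supplied")
  dims <- vapply(epochs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all epochs must share the same shape")
  }
  V <- t(vapply(epochs, flatten_epoch, numeric(prod(dims[, 1]))))
  V <- matrix(V, length(epochs), prod(dims[, 1]))
  labels <- attr(epochs, "joint_labels") %||%
    paste0("joint", seq_len(dims[2, 1]))
  ti <- trial_index %||% attr(epochs, "trial_info") %||%
    tibble(trial_id = seq_along(epochs))
  new_velocity_matrix(V,
                      layout = list(joint_labels = labels,
                                    epoch_samples = dims[1, 1],
                                    n_joints = dims[2, 1]),
                      trial_index = as_tibble(ti))
}

new_velocity_matrix <- function(V, layout, trial_index) {
  stopifnot(ncol(V) == layout$epoch_samples * layout$n_joints,
            nrow(V) == nrow(trial_index))
  structure(list(V = V, layout = layout, trial_index = trial_index),
            class = "velocity_matrix")
}

#' @export
print.velocity_matrix <- function(x, ...) {
  cat("<velocity_matrix> ", nrow(x$V), " trials x ", ncol(x$V),
      " (", x$layout$n_joints, " joints x ", x$layout$epoch_samples,
      " samples, joint-major)\n", sep = "")
  invisible(x)
}

#' Velocity matrix for a whole cohort
#'
#' Segments and stacks every subject's trials into one velocity matrix whose
#' `trial_index` carries the subject id, so train/test subject subsets can be
#' taken by row.
#'
#' @param cohort A `grasp_cohort`.
#' @param epoch_s Epoch length (defaults to the cohort protocol's).
#' @return A `velocity_matrix` with `subject` in its trial index.
#' @export
cohort_velocity <- function(cohort, epoch_s = NULL) {
  stopifnot(inherits(cohort, "grasp_cohort"))
  epoch_s <- epoch_s %||% cohort$protocol$epoch_s
  parts <- purrr::imap(cohort$subjects, function(s, i) {
    ep <- segment_trials(s$kinematics, epoch_s)
    vm <- build_velocity_matrix(ep)
    vm$trial_index$subject <- i
    vm
  })
  V <- do.call(rbind, lapply(parts, `[[`, "V"))
  ti <- dplyr::bind_rows(lapply(parts, `[[`, "trial_index"))
  new_velocity_matrix(V, parts[[1]]$layout, ti)
}

# Subset rows of a velocity_matrix.
vm_subset <- function(vm, rows) {
  new_velocity_matrix(vm$V[rows, , drop = FALSE], vm$layout,
                      vm$trial_index[rows, , drop = FALSE])
}
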
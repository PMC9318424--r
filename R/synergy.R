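#' Singular value decomposition of the velocity matrix
#'
#' Factorizes `V = U diag(d) S` where the rows of `S` are orthonormal
#' spatiotemporal synergy candidates (right singular vectors) and the variance
#' fraction of component i is `d_i^2 / sum(d^2)`. To make the factorization
#' reproducible, each synergy row's sign is fixed so that its
#' largest-magnitude element is positive (the corresponding column of `U` is
#' flipped along with it, so the factorization is unchanged).
#'
#' @param V A `velocity_matrix` or plain numeric matrix.
#' @param center If `TRUE`, column means are removed before decomposition
#'   (covariance-style PCA). Default `FALSE`: the decomposition is applied to
#'   the velocities directly.
#' @return An object of class `synergy_decomposition` with elements `U`, `d`,
#'   `S`, `variance_fractions`, `layout`, `center`.
#' @examples
#' d <- synergy_svd(diag(3))
#' d$variance_fractions  # 1/3, 1/3, 1/3
#' @export
synergy_svd <- function(V, center = FALSE) {
  layout <- NULL
  if (inherits(V, "velocity_matrix")) {
    layout <- V$layout
    V <- V$V
  }
  V <- as.matrix(V)
  if (length(V) == 0 || nrow(V) < 1 || ncol(V) < 1) {
    abort("V must be a non-empty matrix")
  }
  col_means <- rep(0, ncol(V))
  if (center) {
    col_means <- colMeans(V)
    V <- sweep(V, 2, col_means)
  }
  sv <- svd(V)
  S <- t(sv$v)
  # sign convention: largest-|.| element of each synergy positive
  for (i in seq_along(sv$d)) {
    k <- which.max(abs(S[i, ]))
    if (S[i, k] < 0) {
      S[i, ] <- -S[i, ]
      sv$u[, i] <- -sv$u[, i]
    }
  }
  tot <- sum(sv$d^2)
  vf <- if (tot > 0) sv$d^2 / tot else rep(0, length(sv$d))
  structure(list(U = sv$u, d = sv$d, S = S, variance_fractions = vf,
                 layout = layout, center = center, col_means = col_means),
            class = "synergy_decomposition")
}

#' @export
print.synergy_decomposition <- function(x, ...) {
  cat("<synergy_decomposition> ", length(x$d), " components; top variance ",
      "fractions: ", paste(sprintf("%.3f", head(x$variance_fractions, 6)),
                           collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Select synergies by cumulative variance threshold
#'
#' Keeps the smallest leading set of components whose cumulative variance
#' fraction reaches the threshold (inclusive comparison).
#'
#' @param decomp A `synergy_decomposition`.
#' @param threshold Cumulative variance fraction in (0, 1]; default 0.85.
#' @return An object of class `synergy_set` with the selected rows `S`, their
#'   variance fractions, the layout and the threshold used.
#' @export
select_synergies <- function(decomp, threshold = 0.85) {
  stopifnot(inherits(decomp, "synergy_decomposition"))
  if (!is_number(threshold) || threshold <= 0 || threshold > 1) {
    abort("threshold must lie in (0, 1]")
  }
  cum <- cumsum(decomp$variance_fractions)
  n_syn <- which(cum >= threshold - 1e-12)[1]
  if (is.na(n_syn)) n_syn <- length(cum)
  structure(list(S = decomp$S[seq_len(n_syn), , drop = FALSE],
                 variance_fractions = decomp$variance_fractions[seq_len(n_syn)],
                 layout = decomp$layout, threshold = threshold,
                 n_syn = n_syn),
            class = "synergy_set")
}

#' @export
print.synergy_set <- function(x, ...) {
  cat("<synergy_set> ", x$n_syn, " synergies (threshold ", x$threshold,
      "), cumulative variance ", sprintf("%.3f", sum(x$variance_fractions)),
      "\n", sep = "")
  invisible(x)
}

#' Project trials onto the selected synergies
#'
#' Because the synergy rows are orthonormal, the least-squares weights of each
#' trial are the plain projection `C = V S^T`; `C S` is then the best
#' approximation of `V` within the selected synergy span.
#'
#' @param V A `velocity_matrix` (or plain matrix with matching column count).
#' @param synergies A `synergy_set`.
#' @return An object of class `synergy_weights`: list with `C`
#'   (trials x n_syn) and `trial_index`.
#' @export
project_weights <- function(V, synergies) {
  stopifnot(inherits(synergies, "synergy_set"))
  ti <- NULL
  if (inherits(V, "velocity_matrix")) {
    if (!is.null(synergies$layout) &&
        !identical(V$layout$epoch_samples, synergies$layout$epoch_samples)) {
      abort("velocity matrix layout does not match the synergy set")
    }
    ti <- V$trial_index
    V <- V$V
  }
  if (ncol(V) != ncol(synergies$S)) {
    abort("column count of V does not match the synergy set")
  }
  C <- V %*% t(synergies$S)
  new_synergy_weights(C, ti %||% tibble(trial_id = seq_len(nrow(C))))
}

#' Construct a synergy-weight object
#'
#' Pairs a trials x n_syn weight matrix with a trial index. Useful for
#' supplying externally known weights (for instance, a synthetic cohort's
#' ground-truth weights) to functions that normally consume projections.
#'
#' @param C Numeric matrix, trials x synergies.
#' @param trial_index Tibble with one row per trial (defaults to sequential
#'   ids).
#' @return A `synergy_weights` object.
#' @export
synergy_weights <- function(C, trial_index = NULL) {
  C <- as.matrix(C)
  new_synergy_weights(C, trial_index %||% tibble(trial_id = seq_len(nrow(C))))
}

new_synergy_weights <- function(C, trial_index) {
  stopifnot(nrow(C) == nrow(trial_index))
  structure(list(C = as.matrix(C), trial_index = as_tibble(trial_index)),
            class = "synergy_weights")
}

#' @export
print.synergy_weights <- function(x, ...) {
  cat("<synergy_weights> ", nrow(x$C), " trials x ", ncol(x$C),
      " synergies\n", sep = "")
  invisible(x)
}

#' Reconstruct velocity epochs from synergy weights
#'
#' Linearly combines the synergies with the given weights (`v = c^T S` per
#' trial) and returns the result as a `velocity_matrix`, so reconstructed and
#' recorded kinematics can be compared row by row. Use [unflatten_epoch()] or
#' [epoch_list()] to recover per-trial `[samples x joints]` blocks.
#'
#' @param weights A `synergy_weights`.
#' @param synergies The `synergy_set` the weights refer to.
#' @return A `velocity_matrix` of reconstructed velocities (deg/s).
#' @export
reconstruct_velocity <- function(weights, synergies) {
  stopifnot(inherits(weights, "synergy_weights"),
            inherits(synergies, "synergy_set"))
  if (ncol(weights$C) != nrow(synergies$S)) {
    abort("weight columns do not match the number of synergies")
  }
  V <- weights$C %*% synergies$S
  layout <- synergies$layout %||%
    list(joint_labels = paste0("joint", 1L),
         epoch_samples = ncol(V), n_joints = 1L)
  new_velocity_matrix(V, layout, weights$trial_index)
}

#' Per-trial epoch blocks of a velocity matrix
#'
#' @param vm A `velocity_matrix`.
#' @return List of `[epoch_samples x n_joints]` matrices.
#' @export
epoch_list <- function(vm) {
  stopifnot(inherits(vm, "velocity_matrix"))
  lapply(seq_len(nrow(vm$V)), function(i) {
    m <- unflatten_epoch(vm$V[i, ], vm$layout$epoch_samples)
    colnames(m) <- vm$layout$joint_labels
    m
  })
}

#' Reconstruction error versus number of synergies
#'
#' For each synergy count k, reports the normalized reconstruction error
#' `1 - sum_{i<=k} d_i^2 / sum d^2` (tail singular-value energy) and, when
#' `residual = TRUE`, the directly-computed normalized squared Frobenius
#' residual `||V - U_k d_k S_k||^2 / ||V||^2`. The two agree to numerical
#' precision (the optimality of truncated SVD), which makes the pair a useful
#' self-check.
#'
#' @param V The matrix that was decomposed (a `velocity_matrix` or matrix).
#' @param decomp Its `synergy_decomposition`.
#' @param ks Synergy counts to evaluate (default `1:min(rank, 15)`).
#' @param residual Also compute the explicit residual (costs one rank-1 update
#'   per k).
#' @return A tibble with columns `n_synergies`, `error_sv` and (optionally)
#'   `error_residual`.
#' @export
reconstruction_error_curve <- function(V, decomp, ks = NULL, residual = TRUE) {
  stopifnot(inherits(decomp, "synergy_decomposition"))
  if (inherits(V, "velocity_matrix")) V <- V$V
  if (decomp$center) V <- sweep(V, 2, decomp$col_means)
  r <- length(decomp$d)
  ks <- sort(unique(as.integer(ks %||% seq_len(min(r, 15L)))))
  stopifnot(all(ks >= 1), all(ks <= r))
  tot <- sum(decomp$d^2)
  err_sv <- 1 - cumsum(decomp$d^2)[ks] / tot
  out <- tibble(n_synergies = as.integer(ks), error_sv = err_sv)
  if (residual) {
    total_norm <- sum(V^2)
    Vhat <- matrix(0, nrow(V), ncol(V))
    res <- numeric(length(ks))
    kmax <- max(ks)
    pos <- 1L
    for (k in seq_len(kmax)) {
      Vhat <- Vhat + decomp$d[k] *
        tcrossprod(decomp$U[, k], decomp$S[k, ])
      if (k == ks[pos]) {
        res[pos] <- sum((V - Vhat)^2) / total_norm
        pos <- pos + 1L
        if (pos > length(ks)) break
      }
    }
    out$error_residual <- res
  }
  out
}
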
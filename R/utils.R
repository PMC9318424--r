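# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a base seed
#'
#' All randomness in the package flows from one user-supplied integer seed;
#' per-subject, per-fold and per-stage generators are seeded with values derived
#' by a fixed Lehmer step so that substreams are decoupled but reproducible.
#'
#' @param seed Integer base seed.
#' @param k Integer substream index (>= 0).
#' @return An integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, k) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m + 1) * 48271 + 7 * as.numeric(k)
  as.integer(x %% (m - 1) + 1)
}

#' Minimum-norm least squares via singular value decomposition
#'
#' Solves `min ||Y - X B||_F`, returning the minimum-norm solution when `X` is
#' rank deficient. The singular values of `X` are attached so callers can log
#' condition numbers.
#'
#' @param X Numeric matrix of predictors (n x p).
#' @param Y Numeric matrix or vector of responses (n x q).
#' @param tol Relative singular-value cutoff defining the numerical rank.
#' @return A p x q coefficient matrix with attributes `rank` and `cond`.
#' @keywords internal
lstsq_minnorm <- function(X, Y, tol = 1e-10) {
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  sv <- svd(X)
  pos <- sv$d > tol * max(sv$d[1], .Machine$double.eps)
  r <- sum(pos)
  if (r == 0L) {
    B <- matrix(0, ncol(X), ncol(Y))
  } else {
    B <- sv$v[, seq_len(r), drop = FALSE] %*%
      ((crossprod(sv$u[, seq_len(r), drop = FALSE], Y)) / sv$d[seq_len(r)])
  }
  attr(B, "rank") <- r
  attr(B, "cond") <- if (r > 0) sv$d[1] / sv$d[r] else Inf
  attr(B, "rank_deficient") <- r < min(dim(X))
  B
}

# Row-wise Pearson correlation between matching rows of two matrices.
# Rows with zero variance on either side yield NA.
row_cor <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  Ac <- A - rowMeans(A)
  Bc <- B - rowMeans(B)
  num <- rowSums(Ac * Bc)
  den <- sqrt(rowSums(Ac^2) * rowSums(Bc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Periodic Hann taper of length n.
hann_taper <- function(n) {
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
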
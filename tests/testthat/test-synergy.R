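# Helper: a matrix with prescribed singular-value energies.
matrix_with_energies <- function(energies, m = 12, n = 20, seed = 1) {
  set.seed(seed)
  r <- length(energies)
  U <- qr.Q(qr(matrix(rnorm(m * r), m, r)))
  V <- qr.Q(qr(matrix(rnorm(n * r), n, r)))
  U %*% diag(sqrt(energies), r) %*% t(V)
}

test_that("identity and rank-1 matrices decompose as expected", {
  d3 <- synergy_svd(diag(3))
  expect_equal(d3$d, rep(1, 3))
  expect_equal(d3$variance_fractions, rep(1 / 3, 3))

  u <- rnorm(8); s <- rnorm(12)
  d1 <- synergy_svd(outer(u, s))
  expect_equal(sum(d1$d > 1e-10 * d1$d[1]), 1)
  # first right vector is parallel to s
  cs <- abs(sum(d1$S[1, ] * s) / sqrt(sum(s^2)))
  expect_equal(cs, d1$d[1] / d1$d[1], tolerance = 1e-10)
  expect_error(synergy_svd(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("the factorization is exact, sign-deterministic, with orthonormal synergies", {
  set.seed(42)
  V <- matrix(rnorm(30 * 50), 30, 50)
  dec <- synergy_svd(V)
  recon <- dec$U %*% (dec$d * dec$S)
  expect_lt(norm(V - recon, "F") / norm(V, "F"), 1e-10)
  expect_lt(max(abs(tcrossprod(dec$S) - diag(30))), 1e-8)
  expect_identical(dec$S, synergy_svd(V)$S)
  # sign convention: each synergy's largest-magnitude element is positive
  peaks <- apply(dec$S, 1, function(r) r[which.max(abs(r))])
  expect_true(all(peaks > 0))
})

test_that("selection keeps the smallest set reaching the threshold, inclusively", {
  V <- matrix_with_energies(c(0.5, 0.3, 0.2))
  dec <- synergy_svd(V)
  expect_equal(dec$variance_fractions[1:3], c(0.5, 0.3, 0.2),
               tolerance = 1e-10)
  expect_lt(max(dec$variance_fractions[-(1:3)]), 1e-12)
  expect_equal(select_synergies(dec, 0.85)$n_syn, 3)
  expect_equal(select_synergies(dec, 0.80)$n_syn, 2)   # inclusive boundary
  expect_equal(select_synergies(dec, 0.10)$n_syn, 1)
  expect_error(select_synergies(dec, 0), "threshold")
  expect_error(select_synergies(dec, 1.2), "threshold")
})

test_that("noiseless synthetic velocities recover the ground-truth synergy span", {
  sub <- clean_subject()
  gt <- clean_gt()
  vm <- build_velocity_matrix(segment_trials(sub$kinematics, 2))
  dec <- synergy_svd(vm)
  S_est <- dec$S[seq_len(gt$n_syn), ]
  # principal angles between estimated and true spans
  sv <- svd(tcrossprod(S_est, gt$synergies))$d
  angles <- acos(pmin(sv, 1))
  expect_lt(max(angles), 1e-6)
})

test_that("projection weights match the least-squares oracle", {
  sub <- clean_subject()
  vm <- build_velocity_matrix(segment_trials(sub$kinematics, 2))
  syn <- select_synergies(synergy_svd(vm), 0.99)
  W <- project_weights(vm, syn)

  # normal-equations oracle: C = V S' (S S')^{-1}
  oracle <- vm$V %*% t(syn$S) %*% solve(tcrossprod(syn$S))
  expect_equal(W$C, oracle, tolerance = 1e-8)

  # trivial cases
  V2 <- rbind(2 * syn$S[1, ], rep(0, ncol(syn$S)))
  C2 <- project_weights(build_velocity_matrix(
    lapply(1:2, function(i) unflatten_epoch(V2[i, ], 250))), syn)$C
  expect_equal(C2[1, ], c(2, rep(0, syn$n_syn - 1)), tolerance = 1e-10)
  expect_equal(C2[2, ], rep(0, syn$n_syn), tolerance = 1e-10)
})

test_that("reconstruction from projected weights is exact within the span", {
  sub <- clean_subject()
  vm <- build_velocity_matrix(segment_trials(sub$kinematics, 2))
  syn <- select_synergies(synergy_svd(vm), 0.999999)
  W <- project_weights(vm, syn)
  recon <- reconstruct_velocity(W, syn)
  expect_lt(max(abs(recon$V - vm$V)), 1e-8)

  zero <- synergy_weights(matrix(0, 2, syn$n_syn))
  expect_true(all(reconstruct_velocity(zero, syn)$V == 0))
})

test_that("the error curve matches tail singular energy and is non-increasing", {
  di <- synergy_svd(diag(3))
  ec <- reconstruction_error_curve(diag(3), di)
  expect_equal(ec$error_sv, 1 - (1:3) / 3, tolerance = 1e-12)
  expect_equal(ec$error_residual, ec$error_sv, tolerance = 1e-12)

  V <- matrix_with_energies(c(0.4, 0.3, 0.2, 0.1), m = 15, n = 25, seed = 3)
  dec <- synergy_svd(V)
  ec <- reconstruction_error_curve(V, dec)
  expect_lt(max(abs(ec$error_sv - ec$error_residual)), 1e-10)
  expect_true(all(diff(ec$error_sv) <= 1e-12))
  # rank-1 matrix: one synergy reconstructs exactly
  B <- outer(rnorm(5), rnorm(9))
  expect_lt(reconstruction_error_curve(B, synergy_svd(B), ks = 1)$error_sv,
            1e-10)
})
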
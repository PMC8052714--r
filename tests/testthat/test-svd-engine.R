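test_that("bidiagonalization reconstructs the input", {
  # 2x1: single Householder, |d| = column norm
  b <- bidiagonalize(matrix(c(3, 4), 2, 1))
  expect_equal(abs(b$d), 5)
  set.seed(11)
  A <- matrix(rnorm(20 * 5), 20, 5)
  f <- bidiagonalize(A)
  B <- diag(drop(f$d), 5, 5)
  B[cbind(1:4, 2:5)] <- f$e
  expect_lt(norm(f$P %*% B %*% t(f$Q) - A, "F") / norm(A, "F"), 1e-12)
  # orthogonality of the compact factors
  expect_lt(max(abs(crossprod(f$P) - diag(5))), 1e-12)
  expect_lt(max(abs(crossprod(f$Q) - diag(5))), 1e-12)
  expect_error(bidiagonalize(matrix(NaN, 2, 1)), "non-finite")
})

test_that("single-nonzero-column structure bidiagonalizes to a diagonal", {
  K <- structured_K(5, 40, seed = 2)
  f <- bidiagonalize(t(K))
  expect_lt(max(abs(f$e)), 1e-10)
})

test_that("full convergence matches a reference SVD", {
  pol <- stop_policy("full_convergence")
  f <- svd_factorize(diag(c(3, 1)), pol)
  expect_equal(f$sigma, c(3, 1))
  expect_true(all(apply(abs(f$U), 2, max) == 1))
  for (seed in 1:5) {
    set.seed(seed)
    K <- matrix(rnorm(4 * 10), 4, 10)
    f <- svd_factorize(K, pol)
    expect_lt(max(abs(f$sigma - svd(K)$d)), 1e-10)
    expect_lt(f$recon_error, 1e-12)
    expect_false(f$stopped_early)
  }
})

test_that("structured K has the closed-form factorization", {
  # rows are mutually orthogonal, so sigma = sorted row norms and U is a
  # signed permutation
  K <- structured_K(6, 50, seed = 3)
  f <- svd_factorize(K, stop_policy("full_convergence"))
  expect_lt(max(abs(f$sigma - sort(sqrt(rowSums(K^2)), decreasing = TRUE))), 1e-10)
  expect_true(all(apply(abs(f$U), 2, max) >= 1 - 1e-8))
  expect_lt(f$offdiag_norm, 1e-10)
})

test_that("factorization validity holds at every stopping point", {
  set.seed(5)
  K <- matrix(rnorm(6 * 30), 6, 30)
  for (pol in list(stop_policy("full_convergence"),
                   stop_policy("max_sweeps", max_sweeps = 1L),
                   stop_policy("max_sweeps", max_sweeps = 0L),
                   stop_policy("ill_conditioned_guard", near_equal_ratio = 0.5))) {
    f <- svd_factorize(K, pol)
    expect_lt(f$middle_error, 1e-8)
    # orthogonality is preserved by every policy
    expect_lt(max(abs(crossprod(f$U) - diag(nrow(K)))), 1e-10)
    expect_lt(max(abs(tcrossprod(f$Vt) - diag(nrow(K)))), 1e-10)
  }
})

test_that("early stopping mixes left singular vectors on near-equal spectra", {
  # two nearly equal singular values: an interrupted QR phase leaves rotated
  # LSVs, the mechanism behind supporter activity
  set.seed(9)
  D <- diag(c(2, 1.9999, 1.0, 0.5))
  Q1 <- qr.Q(qr(matrix(rnorm(16), 4)))
  Q2 <- qr.Q(qr(matrix(rnorm(64), 8)))[, 1:4]
  K <- Q1 %*% D %*% t(Q2)  # 4 x 4 ... widen below
  K <- cbind(K, matrix(0, 4, 8))
  f_full <- svd_factorize(K, stop_policy("full_convergence"))
  expect_lt(max(abs(f_full$sigma - c(2, 1.9999, 1, 0.5))), 1e-8)
  f_stop <- svd_factorize(K, stop_policy("max_sweeps", max_sweeps = 1L))
  expect_true(f_stop$stopped_early)
  expect_lt(f_stop$middle_error, 1e-8)
  second <- apply(abs(f_stop$U), 2, function(u) sort(u, decreasing = TRUE)[2])
  expect_gt(max(second), 0.10)
})

test_that("guard policy freezes nearly equal blocks and flags early stop", {
  set.seed(13)
  D <- diag(c(3, 2.999, 1))
  Q1 <- qr.Q(qr(matrix(rnorm(9), 3)))
  Q2 <- qr.Q(qr(matrix(rnorm(100), 10)))[, 1:3]
  K <- Q1 %*% D %*% t(Q2)
  f <- svd_factorize(K, stop_policy("ill_conditioned_guard", near_equal_ratio = 1e-2))
  expect_lt(f$middle_error, 1e-8)
  # full convergence on the same matrix is exact
  f2 <- svd_factorize(K, stop_policy("full_convergence"))
  expect_lt(max(abs(f2$sigma - c(3, 2.999, 1))), 1e-8)
})

test_that("minimum-norm solve matches the normal-equations oracle", {
  expect_equal(pseudo_solve(svd_factorize(matrix(c(1, 0), 1, 2),
                                          stop_policy("full_convergence")), 2)$a,
               c(2, 0))
  expect_equal(pseudo_solve(svd_factorize(matrix(c(1, 1), 1, 2),
                                          stop_policy("full_convergence")), 2)$a,
               c(1, 1))
  for (seed in 1:100) {
    set.seed(seed)
    K <- matrix(rnorm(3 * 8), 3, 8)
    b <- rnorm(3)
    f <- svd_factorize(K, stop_policy("full_convergence"))
    a <- pseudo_solve(f, b)$a
    oracle <- drop(t(K) %*% solve(K %*% t(K), b))
    expect_lt(max(abs(a - oracle)), 1e-8)
  }
})

test_that("the minimum-norm solution beats every null-space perturbation", {
  set.seed(21)
  K <- matrix(rnorm(3 * 10), 3, 10)
  b <- rnorm(3)
  f <- svd_factorize(K, stop_policy("full_convergence"))
  a <- pseudo_solve(f, b)$a
  null_basis <- svd(K, nv = 10)$v[, 4:10]
  for (i in 1:100) {
    n <- drop(null_basis %*% rnorm(7))
    expect_lte(sum(a^2), sum((a + n)^2) + 1e-12)
  }
})

test_that("rank handling flags degenerate systems", {
  f <- svd_factorize(matrix(0, 2, 4), stop_policy("full_convergence"))
  expect_warning(sol <- pseudo_solve(f, c(1, 0)), "unsolvable")
  expect_equal(sol$a, rep(0, 4))
  expect_equal(sol$rank_used, 0L)
})

test_that("quality check passes on clean factors and detects corruption", {
  set.seed(31)
  K <- matrix(rnorm(4 * 12), 4, 12)
  b <- rnorm(4)
  f <- svd_factorize(K, stop_policy("full_convergence"))
  sol <- pseudo_solve(f, b)
  rep <- quality_check(f, sol, K, b)
  expect_true(rep$pass)
  bad <- f
  bad$U[1, 1] <- 0
  expect_false(quality_check(bad, sol, K, b)$recon_ok)
  # early-stopped runs report but do not assert the rate residual
  fs <- svd_factorize(K, stop_policy("max_sweeps", max_sweeps = 0L))
  sols <- pseudo_solve(fs, b)
  reps <- quality_check(fs, sols, K, b)
  expect_true(reps$stopped_early)
})
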
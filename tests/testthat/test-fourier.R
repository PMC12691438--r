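test_that("centered FFT is unitary with DC at the grid center", {
  set.seed(1)
  # impulse at the DC index transforms to a flat spectrum of magnitude 1/sqrt(N)
  imp <- matrix(0i, 5, 6)
  imp[5 %/% 2 + 1, 6 %/% 2 + 1] <- 1
  expect_equal(max(abs(Mod(centered_fft(imp, "forward")) - 1 / sqrt(30))), 0)
  expect_equal(centered_fft(matrix(0i, 4, 4)), matrix(0i, 4, 4))
  for (dims in list(c(4, 4), c(5, 7), c(8, 6))) {
    x <- rcmat(dims[1], dims[2])
    X <- centered_fft(x, "forward")
    expect_lt(abs(l2norm(X) - l2norm(x)), 1e-10)                 # Parseval
    expect_lt(max(Mod(centered_fft(X, "inverse") - x)), 1e-10)   # inverse
  }
  expect_error(centered_fft(array(0i, c(2, 2, 2))), "2D")
})

test_that("centered FFT matches the dense shifted DFT matrix", {
  set.seed(2)
  for (dims in list(c(4, 4), c(5, 4))) {
    x <- rcmat(dims[1], dims[2])
    expected <- matrix(dense_dft2(dims[1], dims[2]) %*% as.vector(x),
                       dims[1], dims[2])
    expect_lt(max(Mod(centered_fft(x, "forward") - expected)), 1e-12)
  }
})

test_that("forward operator composes mask, FFT and sensitivities", {
  set.seed(3)
  ny <- 4; nx <- 4
  x <- rcmat(ny, nx)
  S1 <- array(1 + 0i, c(ny, nx, 1))
  full <- matrix(1, ny, nx)
  expect_equal(forward_op(x, S1, full)[, , 1], centered_fft(x, "forward"))
  expect_equal(forward_op(x, S1, matrix(0, ny, nx)),
               array(0i, c(ny, nx, 1)))
  # dense operator oracle, 2 coils, random mask
  S <- rcarr(ny, nx, 2)
  m <- random_mask(ny, nx)
  expected <- array(dense_forward(S, m) %*% as.vector(x), c(ny, nx, 2))
  expect_lt(max(Mod(forward_op(x, S, m) - expected)), 1e-12)
  expect_error(forward_op(rcmat(3, 4), S, m), "mismatch")
})

test_that("adjoint operator is the exact adjoint of the forward operator", {
  set.seed(4)
  S1 <- array(1 + 0i, c(8, 8, 1))
  y1 <- rcarr(8, 8, 1)
  full <- matrix(1, 8, 8)
  expect_equal(adjoint_op(y1, S1, full), centered_fft(y1[, , 1], "inverse"))
  expect_equal(adjoint_op(array(0i, c(8, 8, 1)), S1, full), matrix(0i, 8, 8))
  for (rep in 1:20) {
    S <- rcarr(8, 8, 3)
    m <- random_mask(8, 8)
    x <- rcmat(8, 8)
    y <- rcarr(8, 8, 3)
    lhs <- sum(Conj(forward_op(x, S, m)) * y)
    rhs <- sum(Conj(x) * adjoint_op(y, S, m))
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
  }
})

test_that("CG solves the Tikhonov normal equations to dense-solver accuracy", {
  set.seed(5)
  ny <- 8; nx <- 8
  # identity system: full mask, unit coil, lambda 0 -> one iteration suffices
  S1 <- array(1 + 0i, c(ny, nx, 1))
  rhs <- rcmat(ny, nx)
  expect_lt(max(Mod(cg_normal_solve(rhs, S1, matrix(1, ny, nx), 0, 1) - rhs)),
            1e-12)
  expect_equal(cg_normal_solve(matrix(0i, ny, nx), S1, matrix(1, ny, nx), 0, 5),
               matrix(0i, ny, nx))
  # dense oracle on an R=2 2-coil system for several lambdas
  Sr <- rcarr(ny, nx, 2)
  rss <- sqrt(apply(Mod(Sr)^2, c(1, 2), sum))
  for (c in 1:2) Sr[, , c] <- Sr[, , c] / rss
  m <- mask_grid(make_1d_mask(ny, nx, 2, 1, 0))
  A <- dense_forward(Sr, m)
  AHA <- Conj(t(A)) %*% A
  b <- rcmat(ny, nx)
  for (lam in c(0.1, 1)) {
    dense <- solve(AHA + lam * diag(ny * nx), as.vector(b))
    got <- cg_normal_solve(b, Sr, m, lam, 50)
    expect_lt(l2norm(as.vector(got) - dense) / l2norm(dense), 1e-8)
  }
  # lambda = 0 with a nonsingular A^H A (full mask keeps it invertible)
  dense0 <- solve(Conj(t(dense_forward(Sr, matrix(1, ny, nx)))) %*%
                    dense_forward(Sr, matrix(1, ny, nx)), as.vector(b))
  got0 <- cg_normal_solve(b, Sr, matrix(1, ny, nx), 0, 50)
  expect_lt(l2norm(as.vector(got0) - dense0) / l2norm(dense0), 1e-8)
  expect_error(cg_normal_solve(matrix(NaN + 0i, ny, nx), Sr, m, 0.1, 5), "NaN")
})

test_that("CG residual norm is non-increasing for SPD systems", {
  set.seed(6)
  ny <- 8; nx <- 8
  Sr <- rcarr(ny, nx, 2)
  m <- random_mask(ny, nx)
  b <- rcmat(ny, nx)
  res <- vapply(1:8, function(it) {
    x <- cg_normal_solve(b, Sr, m, 0.5, it)
    l2norm(b - zsrecon:::normal_op(x, Sr, m, 0.5))
  }, numeric(1))
  expect_true(all(diff(res) <= 1e-10))
})

test_that("CG-SENSE recovers well-conditioned undersampled phantoms", {
  truth <- generate_phantom(phantom_spec("shepp_logan", 32, 32, 0.5, seed = 7))
  S <- simulate_coils(coil_spec(4, seed = 8), (Mod(truth) > 0) * 1)
  full <- make_full_mask(32, 32)
  y <- simulate_acquisition(truth, S, full)
  expect_lt(nrmse_pct(cg_sense(y, S, full, 10), truth), 1e-6)
  # R = 2: well-conditioned SENSE, noiseless -> sub-percent error
  m2 <- make_1d_mask(32, 32, 2, 1, 0)
  y2 <- simulate_acquisition(truth, S, m2)
  x2 <- cg_sense(y2, S, m2, 30)
  expect_lt(nrmse_pct(x2, truth), 1)
  # dense cross-check of the same solve at a smaller geometry
  t16 <- generate_phantom(phantom_spec("shepp_logan", 16, 16, 0.5, seed = 7))
  S16 <- simulate_coils(coil_spec(3, seed = 9), (Mod(t16) > 0) * 1)
  m16 <- mask_grid(make_1d_mask(16, 16, 2, 1, 0))
  y16 <- simulate_acquisition(t16, S16, m16)
  A <- dense_forward(S16, m16)
  dense <- solve(Conj(t(A)) %*% A, as.vector(adjoint_op(y16, S16, m16)))
  x16 <- cg_sense(y16, S16, m16, 60)
  expect_lt(l2norm(as.vector(x16) - dense) / l2norm(dense), 1e-6)
  expect_equal(cg_sense(array(0i, dim(y)), S, full, 5), matrix(0i, 32, 32))
  expect_error(cg_sense(y, S, matrix(0, 32, 32), 5), "empty|singular")
})
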
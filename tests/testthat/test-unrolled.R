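zero_model <- function(variant = "zero_mirid", n_unrolls = 2, n_cg = 50,
                       lambda_init = 0.5) {
  m <- unrolled_model(variant, n_unrolls = n_unrolls, n_cg = n_cg,
                      n_layers = 2, channels = 4, lambda_init = lambda_init,
                      seed = 1)
  zw <- function(net) {
    net$W <- lapply(net$W, function(w) array(0, dim(w)))
    net
  }
  m$image_net <- zw(m$image_net)
  if (!is.null(m$kspace_net)) m$kspace_net <- zw(m$kspace_net)
  m
}

test_that("zero-weight model at full sampling is fixed at A^H y", {
  set.seed(1)
  ny <- 8; nx <- 8
  S1 <- array(1 + 0i, c(ny, nx, 1))
  full <- make_full_mask(ny, nx)
  y <- rcarr(ny, nx, 1)
  ahy <- adjoint_op(y, S1, full)
  for (N in c(1, 3)) {
    m <- zero_model(n_unrolls = N)
    expect_lt(max(Mod(unrolled_forward(y, S1, full, m) - ahy)), 1e-10)
  }
  # no unrolls: returns the network input A^H y
  m0 <- zero_model(n_unrolls = 0)
  expect_equal(unrolled_forward(y, S1, full, m0), ahy)
})

test_that("zero-weight model reproduces the dense Tikhonov-anchored iteration", {
  set.seed(2)
  ny <- 8; nx <- 8; C <- 2
  S <- rcarr(ny, nx, C)
  rss <- sqrt(apply(Mod(S)^2, c(1, 2), sum))
  for (c in seq_len(C)) S[, , c] <- S[, , c] / rss
  mask <- make_1d_mask(ny, nx, 2, 1, 0)
  y <- forward_op(rcmat(ny, nx), S, mask)
  model <- zero_model(n_unrolls = 2, n_cg = 60, lambda_init = 0.5)
  got <- unrolled_forward(y, S, mask, model)
  # independent dense implementation: with identity priors, each step solves
  # (A^H A + (l1+l2) I) x = A^H y + (l1+l2) x_prev
  A <- dense_forward(S, mask)
  AHA <- Conj(t(A)) %*% A
  ahy <- as.vector(adjoint_op(y, S, mask))
  lt <- 0.5 + 0.5
  M <- AHA + lt * diag(ny * nx)
  x <- ahy                       # x0 = A^H y, eta0 = zeta0 = x0
  for (n in 1:2) x <- solve(M, ahy + lt * x)
  expect_lt(l2norm(as.vector(got) - x) / l2norm(x), 1e-8)
})

test_that("parameter count is independent of the number of unrolls", {
  m1 <- unrolled_model("zero_mirid", n_unrolls = 1, n_layers = 3, channels = 6)
  m10 <- unrolled_model("zero_mirid", n_unrolls = 10, n_layers = 3, channels = 6)
  expect_identical(n_params(m1), n_params(m10))
  # single-domain variant drops the k-space net and one lambda
  z <- unrolled_model("zs_ssl", n_layers = 3, channels = 6)
  expect_lt(n_params(z), n_params(m1))
  expect_null(z$kspace_net)
  expect_equal(zsrecon:::model_lambdas(z)[["lambda2"]], 0)
})

test_that("gradients flow through the CG solve to the regularization weight", {
  set.seed(3)
  ny <- 8; nx <- 8; C <- 2
  S <- rcarr(ny, nx, C)
  rss <- sqrt(apply(Mod(S)^2, c(1, 2), sum))
  for (c in seq_len(C)) S[, , c] <- S[, , c] / rss
  mask <- make_1d_mask(ny, nx, 2, 1, 2)
  truth <- generate_phantom(phantom_spec("random_ellipses", 16, 16, seed = 4))[1:8, 1:8]
  y <- simulate_acquisition(truth, S, mask, noise_spec(0.01, 5))
  model <- unrolled_model("zero_mirid", n_unrolls = 2, n_cg = 40,
                          n_layers = 2, channels = 4, lambda_init = 0.3,
                          seed = 6)
  # mismatched prior: perturb the final conv layers away from identity
  model$image_net$W[[2]][] <- rnorm(length(model$image_net$W[[2]]), sd = 0.05)
  model$kspace_net$W[[2]][] <- rnorm(length(model$kspace_net$W[[2]]), sd = 0.05)
  part <- partition_kspace(mask, n_pairs = 1, seed = 7, protect_acs = FALSE)
  pr <- part$pairs[[1]]
  spec <- loss_spec("combined")
  slice <- list(kspace = y, sens = S)
  lossfn <- function(m) zsrecon:::slice_pass(slice, pr$lambda, pr$theta, m,
                                             spec, FALSE)$loss
  sp <- zsrecon:::slice_pass(slice, pr$lambda, pr$theta, model, spec, TRUE)
  g_y <- zsrecon:::composite_loss_grad(sp$y_hat, sp$y_ref, pr$theta, spec)
  g_x <- adjoint_op(g_y, S, sp$full)
  gr <- zsrecon:::unrolled_backward(g_x, sp$fw, sp$y_in, S, sp$in_mask, model)
  expect_true(gr$rho1 != 0)
  h <- 1e-5
  for (fld in c("rho1", "rho2")) {
    mp <- model; mp[[fld]] <- mp[[fld]] + h
    mm <- model; mm[[fld]] <- mm[[fld]] - h
    fd <- (lossfn(mp) - lossfn(mm)) / (2 * h)
    expect_lt(abs(fd - gr[[fld]]) / max(abs(fd), 1e-10), 1e-4)
  }
})

test_that("non-finite propagation is reported with the unroll index", {
  ny <- 8; nx <- 8
  S1 <- array(1 + 0i, c(ny, nx, 1))
  y <- rcarr(ny, nx, 1)
  m <- zero_model(n_unrolls = 2, n_cg = 5)
  m$image_net$b[[2]][] <- Inf
  expect_error(unrolled_forward(y, S1, make_full_mask(ny, nx), m),
               "unroll")
})
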
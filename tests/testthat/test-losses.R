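as_ks <- function(v) array(v, c(length(v), 1, 1))

test_that("loss identities: zero at equality, one for the zero prediction", {
  set.seed(1)
  y <- rcarr(6, 6, 2)
  idx <- sort(sample(36, 12))
  zero <- array(0i, dim(y))
  for (p in c(1, 2)) {
    expect_equal(normalized_loss(y, y, idx, p), 0)
    expect_equal(normalized_loss(zero, y, idx, p), 1)
    expect_equal(log_scaled_loss(y, y, idx, p), 0)
    expect_equal(log_scaled_loss(zero, y, idx, p), 1)
  }
  expect_equal(composite_loss(y, y, idx, loss_spec("combined")), 0)
  expect_equal(composite_loss(zero, y, idx, loss_spec("combined")), 4)
  expect_error(normalized_loss(y, zero, idx, 2), "zero")
  expect_error(normalized_loss(y, y, integer(0), 2), "empty")
})

test_that("hand-computed loss values are reproduced", {
  # |3+4i| = 5 residual against itself
  y <- as_ks(3 + 4i)
  expect_equal(normalized_loss(as_ks(0i), y, 1, 2), 1)
  y2 <- as_ks(c(3 + 0i, 4 + 0i))
  expect_equal(normalized_loss(as_ks(c(3 + 0i, 0i)), y2, 1:2, 1), 4 / 7)
  # log-scaled: y = e-1 so log(1+|y|) = 1
  e1 <- exp(1) - 1
  expect_equal(log_scaled_loss(as_ks(0i), as_ks(e1 + 0i), 1, 1), 1)
  # brute-force elementwise oracle on random vectors
  set.seed(2)
  for (p in c(1, 2)) {
    yh <- rcarr(5, 4, 2); yy <- rcarr(5, 4, 2)
    idx <- sort(sample(20, 9))
    r <- yh[idx] - yy[idx]; r <- c(r, yh[idx + 20] - yy[idx + 20])
    v <- c(yy[idx], yy[idx + 20])
    expect_equal(log_scaled_loss(yh, yy, idx, p),
                 sum(log(1 + Mod(r))^p) / sum(log(1 + Mod(v))^p))
    expect_equal(normalized_loss(yh, yy, idx, p),
                 sum(Mod(r)^p)^(1 / p) / sum(Mod(v)^p)^(1 / p))
  }
})

test_that("composite loss is the weighted sum of its terms", {
  set.seed(3)
  yh <- rcarr(4, 4, 1); yy <- rcarr(4, 4, 1)
  idx <- 1:10
  terms <- c(normalized_loss(yh, yy, idx, 1), normalized_loss(yh, yy, idx, 2),
             log_scaled_loss(yh, yy, idx, 1), log_scaled_loss(yh, yy, idx, 2))
  expect_equal(composite_loss(yh, yy, idx, loss_spec("combined")), sum(terms))
  expect_equal(composite_loss(yh, yy, idx, loss_spec("conventional")),
               sum(terms[1:2]))
  expect_equal(composite_loss(yh, yy, idx, loss_spec("log_scaled")),
               sum(terms[3:4]))
  w <- loss_spec("combined", weights = c(l1 = 2, l2 = 1, log_l1 = 0.5,
                                         log_l2 = 3))
  expect_equal(composite_loss(yh, yy, idx, w),
               sum(terms * c(2, 1, 0.5, 3)))
})

test_that("conventional losses are scale-invariant, log-scaled losses are not", {
  set.seed(4)
  yh <- rcarr(4, 4, 2); yy <- rcarr(4, 4, 2)
  idx <- 1:12
  for (alpha in c(0.1, 7)) {
    for (p in c(1, 2)) {
      expect_lt(abs(normalized_loss(alpha * yh, alpha * yy, idx, p) -
                      normalized_loss(yh, yy, idx, p)), 1e-12)
    }
    expect_gt(abs(log_scaled_loss(alpha * yh, alpha * yy, idx, 1) -
                    log_scaled_loss(yh, yy, idx, 1)), 1e-6)
  }
})

test_that("log scaling compresses dynamic range and up-weights spread errors", {
  set.seed(5)
  for (rep in 1:50) {
    r <- sort(exp(runif(2, -3, 3)), decreasing = TRUE)  # r1 > r2 > 0
    expect_lt(log1p(r[1]) / log1p(r[2]), r[1] / r[2])
  }
  # fixed l1 mass: many small residuals yield a larger log-l1 numerator
  # than the same mass concentrated in one entry
  for (rep in 1:20) {
    mass <- exp(runif(1, 0, 3))
    n <- sample(4:32, 1)
    spread <- sum(log1p(rep(mass / n, n)))
    concentrated <- log1p(mass)
    expect_gt(spread, concentrated)
  }
})

test_that("analytic loss gradients match finite differences", {
  set.seed(6)
  yh <- rcarr(4, 4, 2); yy <- rcarr(4, 4, 2)
  idx <- sort(sample(16, 8))
  for (kind in c("conventional", "log_scaled", "combined")) {
    spec <- loss_spec(kind)
    g <- zsrecon:::composite_loss_grad(yh, yy, idx, spec)
    # gradient is zero off the loss subset
    off <- setdiff(seq_len(16), idx)
    expect_true(all(Mod(g[off]) == 0) && all(Mod(g[off + 16]) == 0))
    h <- 1e-6
    for (i in c(idx[1], idx[5] + 16)) {
      yp <- yh; yp[i] <- yp[i] + h
      fdr <- (composite_loss(yp, yy, idx, spec) -
                composite_loss(yh, yy, idx, spec)) / h
      yp <- yh; yp[i] <- yp[i] + 1i * h
      fdi <- (composite_loss(yp, yy, idx, spec) -
                composite_loss(yh, yy, idx, spec)) / h
      expect_lt(Mod(complex(real = fdr, imaginary = fdi) - g[i]) /
                  Mod(g[i]), 1e-4)
    }
  }
})
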
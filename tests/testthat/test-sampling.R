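test_that("1D lattice masks implement acceleration, partial Fourier and ACS", {
  # R=5, 6/8 partial Fourier on 320 lines: 240 retained, every 5th sampled
  m <- make_1d_mask(320, 320, 5, 6 / 8, 0)
  sampled_rows <- which(rowSums(mask_grid(m)) > 0)
  expect_length(sampled_rows, 48)
  expect_equal(sum(mask_grid(m)) / length(mask_grid(m)), 0.15)
  # rows are fully sampled along the frequency-encode axis
  expect_true(all(rowSums(mask_grid(m))[sampled_rows] == 320))
  # R=1, no PF: everything sampled
  expect_true(all(mask_grid(make_1d_mask(16, 16, 1, 1, 0)) == 1))
  # ACS union count oracle by direct enumeration
  ny <- 320
  removed <- (ny - ceiling(0.25 * ny)):(ny - 1)
  retained <- setdiff(0:(ny - 1), removed)
  lattice <- retained[retained %% 5 == (160 %% 5)]
  acs <- (160 - 12):(160 + 11)
  m24 <- make_1d_mask(ny, 8, 5, 6 / 8, 24)
  expect_length(which(rowSums(mask_grid(m24)) > 0),
                length(union(lattice, acs)))
  expect_error(make_1d_mask(32, 32, 2, 17 / 32, 30), "ACS")
})

test_that("partial Fourier removes lines on exactly one side of DC", {
  ny <- 64
  m <- make_1d_mask(ny, 8, 1, 7 / 8, 0)
  rows <- rowSums(mask_grid(m)) > 0
  dc <- ny %/% 2 + 1
  expect_true(all(rows[1:dc]))                  # negative side untouched
  n_rm <- ceiling(ny / 8)
  expect_true(all(!rows[(ny - n_rm + 1):ny]))   # highest positive freqs gone
  # net sampled fraction ~ pf/R within one line
  for (R in c(2, 4)) for (pf in c(1, 7 / 8, 6 / 8)) {
    mm <- make_1d_mask(ny, 8, R, pf, 0)
    frac <- sum(rowSums(mask_grid(mm)) > 0) / ny
    expect_lt(abs(frac - pf / R), 1 / ny + 1e-12)
  }
})

test_that("CAIPI masks form the shifted lattice", {
  m <- make_caipi_mask(18, 18, 3, 3, shift = 1, pf_fraction = 1, acs_width = 0)
  g <- mask_grid(m)
  expect_equal(sum(g), 36)  # exactly 1/9 of 324
  # row offset advances by `shift` every sampled (third) column
  cols <- which(colSums(g) > 0)
  expect_equal(cols, seq(1, 18, by = 3))
  offs <- vapply(cols, function(j) min(which(g[, j] == 1)) - 1L, integer(1))
  expect_equal(diff(offs) %% 3, rep(1L, length(cols) - 1))
  # degenerate cases
  expect_true(all(mask_grid(make_caipi_mask(12, 12, 1, 1, shift = 0)) == 1))
  g0 <- mask_grid(make_caipi_mask(18, 18, 3, 3, shift = 0))
  idx <- which(g0 == 1, arr.ind = TRUE) - 1L
  expect_true(all(idx[, 1] %% 3 == 0) && all(idx[, 2] %% 3 == 0))
})

test_that("k-space partitions are disjoint, exhaustive and reproducible", {
  # counts under the floor rounding rule: |Omega| = 1000 -> 200/320/480
  m <- make_1d_mask(100, 10, 1, 1, 0)  # all 1000 entries acquired
  p <- partition_kspace(m, c(0.48, 0.32, 0.20), n_pairs = 50, seed = 42,
                        protect_acs = FALSE)
  expect_length(p$psi, 200)
  for (pr in p$pairs) {
    expect_length(pr$theta, 320)
    expect_length(pr$lambda, 480)
    expect_equal(sort(c(pr$lambda, pr$theta, p$psi)), p$omega)
    expect_length(intersect(pr$lambda, pr$theta), 0)
    expect_length(intersect(pr$lambda, p$psi), 0)
    expect_length(intersect(pr$theta, p$psi), 0)
  }
  expect_gt(length(unique(vapply(p$pairs, function(pr)
    paste(pr$theta[1:5], collapse = ","), character(1)))), 40)
  # determinism
  p2 <- partition_kspace(m, c(0.48, 0.32, 0.20), n_pairs = 50, seed = 42,
                         protect_acs = FALSE)
  expect_identical(p, p2)
  # indicator masks sum exactly to the Omega indicator
  pr <- p$pairs[[1]]
  total <- subset_mask(pr$lambda, dim(mask_grid(m))) +
    subset_mask(pr$theta, dim(mask_grid(m))) +
    subset_mask(p$psi, dim(mask_grid(m)))
  expect_equal(total, mask_grid(m))
})

test_that("partitions respect the acquisition mask and protect the ACS", {
  m <- make_1d_mask(64, 64, 4, 6 / 8, 8)
  omega <- which(mask_grid(m) == 1)
  p <- partition_kspace(m, n_pairs = 5, seed = 7, protect_acs = TRUE)
  expect_true(all(p$psi %in% omega))
  acs <- m$spec$acs_idx
  expect_length(intersect(p$psi, acs), 0)
  for (pr in p$pairs) {
    expect_true(all(pr$lambda %in% omega) && all(pr$theta %in% omega))
    expect_true(all(acs %in% pr$lambda))
  }
  expect_error(partition_kspace(m, c(0.1, 0.1, 0.8), n_pairs = 1, seed = 1),
               "infeasible|sum to 1")
  expect_error(partition_kspace(m, c(0.98 / 3, 0.98 / 3, 0.98 / 3),
                                n_pairs = 1, seed = 1), "sum to 1")
})
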
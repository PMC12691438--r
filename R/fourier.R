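#' Centered orthonormal Fourier transforms and SENSE operators
#'
#' The encoding model for parallel MRI is `y_c = F S_c x + eps_c`: each of C
#' receiver coils measures the Fourier transform of the object `x` weighted by
#' its complex sensitivity profile `S_c`.  Acceleration samples only a subset
#' `Omega` of k-space, `y_{c,Omega} = P_Omega F S_c x + eps_c`.  All transforms
#' in this package are unitary (1/sqrt(N) in both directions) with the DC
#' component at grid index `floor(N/2)` (0-based), implemented as
#' shift--transform--shift.  Unitarity makes Parseval exact and the normal
#' operator `A^H A` spectrally bounded by 1, which keeps loss normalisation and
#' Tikhonov weights on a common scale.
#'
#' @name fourier-ops
NULL

# cached fftshift/ifftshift index vectors per axis length
.shift_cache <- new.env(parent = emptyenv())

shift_idx <- function(n) {
  key <- as.character(n)
  got <- .shift_cache[[key]]
  if (!is.null(got)) return(got)
  s <- n %/% 2
  out <- list(f = ((seq_len(n) - 1 - s) %% n) + 1L,   # fftshift
              i = ((seq_len(n) - 1 + s) %% n) + 1L)   # ifftshift
  .shift_cache[[key]] <- out
  out
}

# Batched centered unitary 2D FFT over the first two dims of a 3D array,
# one transform per slice of the third dim (coils / channels).
cfft_mc <- function(a, direction) {
  d <- dim(a); ny <- d[1]; nx <- d[2]; C <- d[3]
  sy <- shift_idx(ny); sx <- shift_idx(nx)
  inv <- direction == "inverse"
  a <- a[sy$i, sx$i, , drop = FALSE]
  dim(a) <- c(ny, nx * C)
  a <- stats::mvfft(a, inverse = inv)
  dim(a) <- d
  a <- aperm(a, c(2, 1, 3))
  dim(a) <- c(nx, ny * C)
  a <- stats::mvfft(a, inverse = inv)
  dim(a) <- c(nx, ny, C)
  a <- aperm(a, c(2, 1, 3))
  a[sy$f, sx$f, , drop = FALSE] / sqrt(ny * nx)
}

#' Centered unitary 2D Fourier transform
#'
#' Computes the orthonormal DFT of a 2D complex image with the zero-frequency
#' (DC) coefficient at index `floor(N/2)` along each axis (0-based), i.e.
#' `fftshift(fft(ifftshift(x))) / sqrt(ny*nx)`.  The inverse direction is the
#' exact adjoint and inverse of the forward direction.
#'
#' @param img complex matrix (ny x nx).
#' @param direction `"forward"` or `"inverse"`.
#' @return complex matrix of the same shape.
#' @export
centered_fft <- function(img, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (!is.matrix(img)) stop("centered_fft: input must be a 2D matrix")
  out <- cfft_mc(array(img, c(dim(img), 1L)), direction)
  dim(out) <- dim(img)
  out
}

stopifnot_geometry <- function(x, S, mask) {
  dS <- dim(S)
  if (length(dS) != 3L)
    stop("sensitivities must be a (ny x nx x C) array")
  if (!is.matrix(x) || any(dim(x) != dS[1:2]))
    stop("image/sensitivity shape mismatch")
  g <- mask_grid(mask)
  if (any(dim(g) != dS[1:2]))
    stop("mask/sensitivity shape mismatch")
  invisible(TRUE)
}

#' SENSE forward operator A = P_Omega F S
#'
#' Per coil: multiply by the sensitivity map, take the centered unitary FFT,
#' and zero the unsampled k-space locations.
#'
#' @param x complex image matrix (ny x nx).
#' @param S complex sensitivity array (ny x nx x C).
#' @param mask a [sampling_mask] or binary matrix (ny x nx).
#' @return complex multicoil k-space array (ny x nx x C), zero where unsampled.
#' @export
forward_op <- function(x, S, mask) {
  stopifnot_geometry(x, S, mask)
  g <- mask_grid(mask)
  C <- dim(S)[3]
  y <- cfft_mc(S * array(x, dim(S)), "forward")
  y * array(g, dim(S))
}

#' SENSE adjoint operator A^H
#'
#' `sum_c conj(S_c) * F^H (P_Omega y_c)`; the exact adjoint of [forward_op()]
#' under the unitary FFT convention.  With unit root-sum-of-squares
#' sensitivities and full sampling, `A^H A` is the identity, so `A^H y` is the
#' coil-combined zero-filled reconstruction used as network input.
#'
#' @inheritParams forward_op
#' @param y complex multicoil k-space array (ny x nx x C).
#' @return complex image matrix (ny x nx).
#' @export
adjoint_op <- function(y, S, mask) {
  dS <- dim(S)
  if (length(dim(y)) != 3L || any(dim(y) != dS))
    stop("kspace/sensitivity shape mismatch")
  g <- mask_grid(mask)
  if (any(dim(g) != dS[1:2])) stop("mask/sensitivity shape mismatch")
  z <- Conj(S) * cfft_mc(y * array(g, dS), "inverse")
  matrix(rowSums(matrix(z, dS[1] * dS[2], dS[3])), dS[1], dS[2])
}

normal_op <- function(x, S, mask, lambda_total) {
  adjoint_op(forward_op(x, S, mask), S, mask) + lambda_total * x
}

ifftshift2 <- function(m) {
  m[shift_idx(nrow(m))$i, shift_idx(ncol(m))$i, drop = FALSE]
}

# A^H A x + lambda x evaluated in unshifted k-space coordinates: the shift
# permutations around the elementwise mask cancel when the mask itself is
# ifftshift-ed, so the CG inner loop runs plain FFTs with no index shuffles.
normal_op_fast <- function(x, S, mask_unshifted, lambda_total, C, N) {
  acc <- lambda_total * x
  for (c in seq_len(C)) {
    z <- stats::fft(S[, , c] * x)
    z <- stats::fft(mask_unshifted * z, inverse = TRUE)
    acc <- acc + Conj(S[, , c]) * z
  }
  acc  # the two unnormalized FFTs cancel up to 1/N, folded into the mask
}

#' Conjugate-gradient solve of the Tikhonov normal equations
#'
#' Runs a fixed number of complex conjugate-gradient iterations on the
#' Hermitian positive (semi-)definite system
#' `(A^H A + lambda_total I) x = rhs`, starting from `x = 0`.  This is the
#' data-consistency block of the unrolled network; ten iterations is the
#' model default.  No tolerance-based early exit is performed unless `tol > 0`.
#'
#' @inheritParams forward_op
#' @param rhs complex image matrix, the right-hand side (typically
#'   `A^H y + lambda1*eta + lambda2*zeta`).
#' @param lambda_total nonnegative Tikhonov weight added to `A^H A`.
#' @param n_iter number of CG iterations (>= 1).
#' @param tol optional relative-residual stopping tolerance (0 disables).
#' @return complex image matrix.
#' @export
cg_normal_solve <- function(rhs, S, mask, lambda_total, n_iter = 10, tol = 0) {
  if (anyNA(rhs) || anyNA(S)) stop("cg_normal_solve: NaN in inputs")
  if (lambda_total < 0) stop("lambda_total must be nonnegative")
  if (n_iter < 1) stop("n_iter must be >= 1")
  x <- matrix(0i, nrow(rhs), ncol(rhs))
  r <- rhs
  p <- r
  rs_old <- Re(sum(Conj(r) * r))
  rs0 <- rs_old
  if (rs0 == 0) return(x)
  C <- dim(S)[3]
  mu <- ifftshift2(mask_grid(mask)) / length(rhs)
  for (it in seq_len(n_iter)) {
    Ap <- normal_op_fast(p, S, mu, lambda_total, C, length(rhs))
    pAp <- Re(sum(Conj(p) * Ap))
    if (pAp <= 0) break  # numerical null-space direction; nothing to gain
    alpha <- rs_old / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- Re(sum(Conj(r) * r))
    if (!is.finite(rs_new) || rs_new > 1e12 * rs0)
      stop(sprintf("cg_normal_solve: divergence at iteration %d (residual ratio %.3g)",
                   it, rs_new / rs0))
    if (tol > 0 && sqrt(rs_new / rs0) < tol) break
    p <- r + (rs_new / rs_old) * p
    rs_old <- rs_new
  }
  x
}

#' CG-SENSE reconstruction
#'
#' Unregularised least-squares SENSE: solves
#' `argmin_x ||P_Omega F S x - y_Omega||^2` by conjugate gradients on the
#' normal equations with `lambda_total = 0`.
#'
#' @inheritParams adjoint_op
#' @param n_iter number of CG iterations.
#' @return complex image matrix.
#' @export
cg_sense <- function(y, S, mask, n_iter = 10) {
  g <- mask_grid(mask)
  if (sum(g) == 0) stop("cg_sense: empty sampling mask (singular system)")
  cg_normal_solve(adjoint_op(y, S, mask), S, mask, 0, n_iter)
}
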